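# End-to-end pipeline over a synthetic study: simulate -> standardize ->
# cluster -> classify -> situation similarity -> association -> valence.
# All randomness flows from the seeds recorded in the config, so a rerun
# with the same config reproduces every table.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one declarative object:
#' the synthetic study design, clustering and permutation settings, the
#' multi-call simulation grid, and per-stage seeds derived from one master
#' seed.
#'
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param design a [study_design()].
#' @param sd_scale prototype blur passed to [call_prototypes()].
#' @param kmax largest cluster number for the validity curve.
#' @param n_restarts k-means restarts per K.
#' @param n_perm label/subject permutations for significance tests.
#' @param n_mc Monte-Carlo replicates for the association chi-square.
#' @param n_range multi-call sample sizes.
#' @param inner,outer multi-call simulation repetitions.
#' @param n_experts,swap_noise expert-panel simulation settings.
#' @param fdr_q FDR level used when flagging adjusted p-values.
#' @param out_dir optional directory; when set, [run_pipeline()] writes
#'   all result tables there.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1, design = study_design(),
                            sd_scale = 1, kmax = 15, n_restarts = 50,
                            n_perm = 1000, n_mc = 2000, n_range = 1:20,
                            inner = 10, outer = 20, n_experts = 28,
                            swap_noise = 0.2, fdr_q = 0.05,
                            out_dir = NULL) {
  seed <- as.integer(seed)
  structure(list(
    seed = seed, design = design, sd_scale = sd_scale, kmax = kmax,
    n_restarts = n_restarts, n_perm = n_perm, n_mc = n_mc,
    n_range = n_range, inner = inner, outer = outer,
    n_experts = n_experts, swap_noise = swap_noise, fdr_q = fdr_q,
    out_dir = out_dir,
    stage_seeds = list(simulate = seed, cluster = seed + 101L,
                       classify = seed + 202L, curve = seed + 303L,
                       association = seed + 404L, experts = seed + 505L)
  ), class = "pipeline_config")
}

write_tsv <- function(x, dir, name) {
  utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full repertoire analysis pipeline on a synthetic study
#'
#' Simulates the call dataset, standardizes features, computes the
#' EtaK/PreK validity curve and the named 2- and 5-cluster solutions,
#' classifies calls to situations (acoustic and call-type predictors, 11
#' situations and gross categories) with permutation and pDFA
#' significance, runs the multi-call accuracy simulation, builds Ward
#' dendrograms and type-situation association tables, and fits the valence
#' models against a simulated expert panel.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class \code{"pipeline_result"} with all stage outputs;
#'   when \code{config$out_dir} is set the tables are also written there
#'   as delimited text plus a JSON run report.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  ss <- config$stage_seeds

  say("simulate: generating call dataset")
  protos <- call_prototypes(config$sd_scale)
  calls <- simulate_calls(config$design, protos, seed = ss$simulate)
  fn <- feature_names()

  say("extract: standardizing and screening features")
  scaling <- standardize_features(calls[, fn])
  retained <- screen_variables(calls[, fn])
  z <- scaling$z[, retained, drop = FALSE]

  say("cluster: validity curve K = 1..", config$kmax)
  curve <- validity_curve(z, kmax = config$kmax,
                          n_restarts = config$n_restarts,
                          seed = ss$cluster)
  sol2 <- curve$solutions[[2]]
  sol5 <- curve$solutions[[5]]
  names2 <- name_call_types(sol2, calls)
  names5 <- name_call_types(sol5, calls)
  type2 <- unname(names2[as.character(sol2$assignments)])
  type5 <- unname(names5[as.character(sol5$assignments)])
  nesting <- nesting_crosstab(sol2, sol5)
  reps <- lapply(seq_len(5), function(k)
    representative_call(z, sol5, k))
  loadings <- cluster_dfa_loadings(z, type5)

  say("classify: holdout + permutation significance")
  cls_ac <- permutation_significance(z, calls$situation,
                                     n_perm = config$n_perm,
                                     seed = ss$classify)
  cls_t5 <- permutation_significance(dummy_code_types(type5),
                                     calls$situation,
                                     n_perm = config$n_perm,
                                     seed = ss$classify + 1L,
                                     ridge = 1e-8)
  pdfa_ac <- pdfa(z, calls$situation, calls$piglet,
                  n_perm = config$n_perm, seed = ss$classify + 2L)
  mano <- manova_wilks(z, calls$situation)
  gross <- gross_category(calls$situation)
  cls_gross <- holdout_classification(z, gross, seed = ss$classify + 3L)

  say("curve: multi-call accuracy simulation")
  curves <- list(
    acoustic_situation = multi_call_accuracy(
      z, calls$situation, n_range = config$n_range,
      inner = config$inner, outer = config$outer, seed = ss$curve),
    types5_situation = multi_call_accuracy(
      type5, calls$situation, n_range = config$n_range,
      inner = config$inner, outer = config$outer, seed = ss$curve + 1L,
      mode = "types"),
    acoustic_gross = multi_call_accuracy(
      z, gross, n_range = config$n_range,
      inner = config$inner, outer = config$outer, seed = ss$curve + 2L),
    types5_gross = multi_call_accuracy(
      type5, gross, n_range = config$n_range,
      inner = config$inner, outer = config$outer, seed = ss$curve + 3L,
      mode = "types")
  )

  say("similarity + association")
  prof_ac <- situation_profiles(calls, "acoustic")
  prof_t5 <- situation_profiles(
    data.frame(situation = calls$situation, type = type5), "types")
  prof_t2 <- situation_profiles(
    data.frame(situation = calls$situation, type = type2), "types")
  dendros <- list(acoustic = ward_dendrogram(prof_ac),
                  types2 = ward_dendrogram(prof_t2),
                  types5 = ward_dendrogram(prof_t5))
  assoc2 <- association_test(type2, calls$situation, n_mc = config$n_mc,
                             seed = ss$association)
  assoc5 <- association_test(type5, calls$situation, n_mc = config$n_mc,
                             seed = ss$association + 1L)

  say("valence: expert panel + models")
  ranks <- simulate_expert_ranks(config$design$valence_order,
                                 n_experts = config$n_experts,
                                 swap_noise = config$swap_noise,
                                 seed = ss$experts)
  valence <- mean_valence(ranks)
  spear <- valence_feature_correlation(prof_ac, valence)
  reg5 <- valence_type_regression(table(calls$situation, type5), valence)
  reg2 <- valence_type_regression(table(calls$situation, type2), valence)

  result <- structure(list(
    config = config, calls = calls, scaling = scaling,
    retained_variables = retained, validity = curve,
    solution2 = sol2, solution5 = sol5,
    type_names = list(k2 = names2, k5 = names5),
    type2 = type2, type5 = type5, nesting = nesting,
    representatives = reps, loadings = loadings,
    classification = list(acoustic = cls_ac, types5 = cls_t5,
                          pdfa_acoustic = pdfa_ac, gross = cls_gross),
    manova = mano, accuracy_curves = curves,
    profiles = list(acoustic = prof_ac, types2 = prof_t2,
                    types5 = prof_t5),
    dendrograms = dendros,
    association = list(types2 = assoc2, types5 = assoc5),
    expert_ranks = ranks, valence = valence,
    valence_models = list(spearman = spear, types5 = reg5, types2 = reg2)
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Vocal repertoire pipeline result\n")
  cat("calls:", nrow(x$calls), "in",
      length(unique(x$calls$situation)), "situations\n")
  cat("EtaK(2) =", round(x$validity$table$etaK[2], 3),
      "; EtaK(5) =", round(x$validity$table$etaK[5], 3), "\n")
  cat("single-call accuracy (acoustic):",
      round(x$classification$acoustic$percent_correct, 1), "% (chance",
      round(x$classification$acoustic$chance_percent, 1), "%, p =",
      format.pval(x$classification$acoustic$p_value, digits = 3), ")\n")
  cat("MANOVA Wilks lambda =", round(x$manova$wilks_lambda, 3), "\n")
  invisible(x)
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assignments <- data.frame(call_id = result$calls$call_id,
                            situation = result$calls$situation,
                            K2_label = result$type2,
                            K5_label = result$type5)
  write_tsv(assignments, out_dir, "assignments.tsv")
  write_tsv(result$validity$table, out_dir, "validity_curve.tsv")
  write_tsv(cbind(situation = rownames(result$profiles$acoustic),
                  as.data.frame(result$profiles$acoustic)),
            out_dir, "profiles_acoustic.tsv")
  for (nm in names(result$accuracy_curves))
    write_tsv(result$accuracy_curves[[nm]], out_dir,
              paste0("accuracy_", nm, ".tsv"))
  for (nm in names(result$dendrograms))
    writeLines(result$dendrograms[[nm]]$newick,
               file.path(out_dir, paste0("dendrogram_", nm, ".nwk")))
  write_tsv(as.data.frame(result$valence_models$spearman), out_dir,
            "valence_spearman.tsv")
  write_tsv(as.data.frame(result$valence_models$types5), out_dir,
            "valence_types5.tsv")
  report <- list(
    package_version = as.character(utils::packageVersion("vocrep")),
    seeds = result$config$stage_seeds,
    settings = result$config[c("sd_scale", "kmax", "n_restarts", "n_perm",
                               "n_mc", "inner", "outer", "n_experts",
                               "swap_noise", "fdr_q")],
    n_calls = nrow(result$calls),
    etaK2 = result$validity$table$etaK[2],
    single_call_accuracy = result$classification$acoustic$percent_correct,
    p_value = result$classification$acoustic$p_value,
    wilks_lambda = result$manova$wilks_lambda
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
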