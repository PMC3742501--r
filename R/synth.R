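# Synthetic call generator: latent call-type prototypes, a study design with
# situation-specific type mixtures and piglet/litter random effects, and a
# deterministic waveform synthesizer so the acoustic front-end can be
# exercised end-to-end without field recordings.

feature_names <- function() {
  c("pf", "q50", "ent", "q50start", "q50end", "q50min", "dur", "q50maxloc")
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  code
}

#' Default call-type prototypes
#'
#' Five latent call-type prototypes spanning the qualitative structure of a
#' piglet repertoire: three low-frequency types (stable LFs, frequency
#' modulated LFm, tonal LFt) and two high-frequency types (stable HFs,
#' strongly upward-modulated HFm). HF types are higher pitched and longer
#' than LF types; LFs is the lowest and least modulated; LFt has the highest
#' q50 and lowest entropy among LF calls. Each prototype carries the mean and
#' standard deviation of the 8 acoustic features in natural units, plus the
#' parameters used for waveform synthesis (fundamental sweep end-points,
#' tonal fraction, mean duration).
#'
#' @param sd_scale multiplier applied to every feature standard deviation;
#'   1 gives a realistically blurred repertoire, small values give
#'   well-separated types for recovery experiments.
#' @return list of prototypes, each a list with \code{label},
#'   \code{mean_features} (named 8-vector), \code{feature_sd},
#'   \code{f_start}, \code{f_end}, \code{tonal_fraction}, \code{dur_mean}.
#' @export
call_prototypes <- function(sd_scale = 1) {
  stopifnot(is.numeric(sd_scale), sd_scale >= 0)
  fn <- feature_names()
  proto <- function(label, mean, sd, f_start, f_end, tonal, dur) {
    names(mean) <- fn
    names(sd) <- fn
    list(label = label, mean_features = mean, feature_sd = sd * sd_scale,
         f_start = f_start, f_end = f_end, tonal_fraction = tonal,
         dur_mean = dur)
  }
  # within-type sds are broad on purpose: the emulated repertoire is graded,
  # with heavy overlap between neighbouring types, and the pitch variables
  # must stay below the |r| > 0.9 screening threshold across the table
  list(
    LFs = proto("LFs",
      mean = c(300, 500, 0.75, 520, 500, 300, 0.15, 5),
      sd   = c(500, 450, 0.10, 500, 480, 380, 0.08, 2.0),
      f_start = 480, f_end = 500, tonal = 0.15, dur = 0.15),
    LFm = proto("LFm",
      mean = c(420, 850, 0.62, 620, 1150, 400, 0.20, 8),
      sd   = c(450, 450, 0.10, 480, 520, 380, 0.10, 1.5),
      f_start = 600, f_end = 1150, tonal = 0.35, dur = 0.20),
    LFt = proto("LFt",
      mean = c(950, 1250, 0.30, 1130, 1180, 820, 0.26, 5),
      sd   = c(500, 450, 0.08, 480, 480, 380, 0.12, 2.0),
      f_start = 1150, f_end = 1200, tonal = 0.85, dur = 0.26),
    HFs = proto("HFs",
      mean = c(3600, 3850, 0.33, 3650, 3720, 3050, 0.92, 5),
      sd   = c(700, 600, 0.08, 650, 650, 500, 0.35, 2.0),
      f_start = 3650, f_end = 3750, tonal = 0.8, dur = 0.92),
    HFm = proto("HFm",
      mean = c(2500, 3050, 0.40, 1850, 4250, 1450, 0.55, 9),
      sd   = c(700, 600, 0.08, 600, 650, 460, 0.25, 1.3),
      f_start = 1800, f_end = 4300, tonal = 0.7, dur = 0.55)
  )
}

#' Default situation-specific call-type mixtures
#'
#' Probability of each latent call type per situation, chosen so that
#' high-frequency types concentrate in life-threatening situations, tonal
#' low-frequency calls in nursing situations, and stable/modulated
#' low-frequency calls in the general social situations.
#'
#' @return matrix with situations as rows, call types as columns; rows sum
#'   to 1.
#' @export
default_type_mixtures <- function() {
  types <- c("LFs", "LFm", "LFt", "HFs", "HFm")
  m <- rbind(
    CA = c(0.05, 0.05, 0.10, 0.45, 0.35),
    CR = c(0.10, 0.10, 0.15, 0.25, 0.40),
    AR = c(0.10, 0.10, 0.10, 0.25, 0.45),
    FI = c(0.10, 0.10, 0.15, 0.20, 0.45),
    BN = c(0.10, 0.15, 0.55, 0.05, 0.15),
    AN = c(0.10, 0.15, 0.60, 0.05, 0.10),
    MN = c(0.25, 0.25, 0.30, 0.05, 0.15),
    HU = c(0.40, 0.30, 0.20, 0.02, 0.08),
    IS = c(0.55, 0.25, 0.15, 0.02, 0.03),
    RE = c(0.20, 0.45, 0.30, 0.02, 0.03),
    SU = c(0.40, 0.35, 0.15, 0.05, 0.05)
  )
  colnames(m) <- types
  m
}

#' Construct a synthetic study design
#'
#' Bundles situation metadata (call/piglet/litter counts), situation-specific
#' call-type mixtures, the scale of per-piglet and per-litter additive random
#' effects (expressed as multiples of the within-type feature standard
#' deviation), and the true negativity ordering of the situations.
#'
#' @param situations data.frame as returned by [piglet_situations()];
#'   columns \code{situation}, \code{n_calls}, \code{n_piglets},
#'   \code{n_litters} are required.
#' @param mixtures situations-by-types probability matrix; rows must sum
#'   to 1 and row names must cover all situations in \code{situations}.
#' @param piglet_sd,litter_sd random-effect scales (standardized units).
#' @param valence_order character vector of situation codes ordered from
#'   most negative (rank 1) to most positive; defaults to the expert
#'   consensus ordering for the canonical 11 situations, or the design's
#'   own situation order otherwise.
#' @return an object of class \code{"study_design"}.
#' @export
study_design <- function(situations = piglet_situations(),
                         mixtures = default_type_mixtures(),
                         piglet_sd = 0.5, litter_sd = 0.25,
                         valence_order = NULL) {
  if (is.null(valence_order)) {
    canonical <- c("CA", "CR", "IS", "AR", "MN", "FI", "SU", "BN", "HU",
                   "RE", "AN")
    valence_order <- if (setequal(situations$situation, canonical) &&
                           nrow(situations) == 11) canonical
                     else situations$situation
  }
  stopifnot(is.data.frame(situations),
            all(c("situation", "n_calls", "n_piglets", "n_litters") %in%
                  names(situations)))
  if (anyDuplicated(situations$situation))
    stop("duplicate situation codes in design")
  if (any(situations$n_calls < 1)) stop("each situation needs n_calls >= 1")
  if (piglet_sd < 0 || litter_sd < 0) stop("random-effect sds must be >= 0")
  miss <- setdiff(situations$situation, rownames(mixtures))
  if (length(miss))
    stop("no mixture row for situation(s): ", paste(miss, collapse = ", "))
  mixtures <- mixtures[situations$situation, , drop = FALSE]
  if (any(mixtures < 0) || ncol(mixtures) == 0)
    stop("mixtures must be non-negative probabilities")
  rs <- rowSums(mixtures)
  if (any(abs(rs - 1) > 1e-9))
    stop("mixture rows must sum to 1 (off rows: ",
         paste(rownames(mixtures)[abs(rs - 1) > 1e-9], collapse = ", "), ")")
  vo <- as.character(valence_order)
  if (!setequal(vo, situations$situation) ||
      length(vo) != nrow(situations))
    stop("valence_order must be a permutation of the situation codes")
  structure(list(situations = situations, mixtures = mixtures,
                 piglet_sd = piglet_sd, litter_sd = litter_sd,
                 valence_order = vo),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Synthetic study design:", nrow(x$situations), "situations,",
      sum(x$situations$n_calls), "calls,",
      ncol(x$mixtures), "latent call types\n")
  cat("piglet_sd =", x$piglet_sd, ", litter_sd =", x$litter_sd, "\n")
  invisible(x)
}

#' Simulate a call feature table from a study design
#'
#' Draws one latent call type per call from the situation's mixture and
#' generates the 8 acoustic features as prototype mean + litter offset +
#' piglet offset + residual Gaussian noise. Offsets are shared by all calls
#' of a piglet (litter), making individual non-independence available to
#' downstream permutation tests. Each piglet belongs to exactly one litter
#' and, by default, appears in a single situation.
#'
#' @param design a [study_design()].
#' @param prototypes list of call-type prototypes, as [call_prototypes()];
#'   must cover every column of the design's mixture matrix.
#' @param seed integer seed; the output is reproducible given the seed.
#' @return data.frame with one row per call: \code{call_id},
#'   \code{situation}, \code{gross}, \code{piglet}, \code{litter},
#'   \code{type} (true latent label) and the 8 feature columns.
#' @examples
#' calls <- simulate_calls(study_design(), call_prototypes(), seed = 1)
#' nrow(calls)   # 1513
#' @export
simulate_calls <- function(design, prototypes = call_prototypes(),
                           seed = 1) {
  stopifnot(inherits(design, "study_design"))
  types <- colnames(design$mixtures)
  miss <- setdiff(types, names(prototypes))
  if (length(miss))
    stop("no prototype for call type(s): ", paste(miss, collapse = ", "))
  fn <- feature_names()
  for (p in prototypes)
    if (any(p$feature_sd < 0)) stop("negative feature sd in prototype ", p$label)
  mu <- t(vapply(prototypes[types], function(p) p$mean_features[fn],
                 numeric(8)))
  sdm <- t(vapply(prototypes[types], function(p) p$feature_sd[fn],
                  numeric(8)))
  ref_scale <- colMeans(sdm)        # per-feature scale for random effects

  with_seed(seed, {
    sit <- design$situations
    rows <- vector("list", nrow(sit))
    for (i in seq_len(nrow(sit))) {
      s <- sit$situation[i]
      n <- sit$n_calls[i]
      np <- min(sit$n_piglets[i], n)
      nl <- min(sit$n_litters[i], np)
      piglet_ids <- sprintf("%s_p%02d", s, seq_len(np))
      litter_ids <- sprintf("%s_l%02d", s, seq_len(nl))
      piglet_litter <- litter_ids[1 + (seq_len(np) - 1) %% nl]
      # spread calls evenly over piglets
      call_piglet <- piglet_ids[1 + (seq_len(n) - 1) %% np]
      type <- sample(types, n, replace = TRUE,
                     prob = design$mixtures[s, ])
      lit_off <- matrix(stats::rnorm(nl * 8), nl, 8) *
        rep(design$litter_sd * ref_scale, each = nl)
      pig_off <- matrix(stats::rnorm(np * 8), np, 8) *
        rep(design$piglet_sd * ref_scale, each = np)
      ti <- match(type, types)
      pi <- match(call_piglet, piglet_ids)
      li <- match(piglet_litter[pi], litter_ids)
      feat <- mu[ti, , drop = FALSE] +
        pig_off[pi, , drop = FALSE] + lit_off[li, , drop = FALSE] +
        matrix(stats::rnorm(n * 8), n, 8) * sdm[ti, , drop = FALSE]
      colnames(feat) <- fn
      rows[[i]] <- data.frame(
        situation = s, piglet = call_piglet,
        litter = piglet_litter[pi], type = type, feat,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    # keep generated features physically admissible
    for (v in c("pf", "q50", "q50start", "q50end", "q50min"))
      out[[v]] <- pmax(out[[v]], 40)
    out$dur <- pmax(out$dur, 0.034)
    out$ent <- pmin(pmax(out$ent, 0), 1)
    out$q50maxloc <- pmin(pmax(round(out$q50maxloc), 1), 9)
    out$q50min <- pmin(out$q50min, out$q50start, out$q50end)
    out <- data.frame(call_id = sprintf("c%04d", seq_len(nrow(out))),
                      out, stringsAsFactors = FALSE)
    out$gross <- gross_category(out$situation)
    rownames(out) <- NULL
    out[, c("call_id", "situation", "gross", "piglet", "litter", "type", fn)]
  })
}

#' Synthesize one call waveform from a prototype
#'
#' Builds a deterministic test signal: a harmonic stack whose fundamental
#' sweeps linearly from \code{f_start} to \code{f_end}, energy-mixed with
#' white noise according to the prototype's tonal fraction, amplitude-tapered
#' at the edges and embedded in leading/trailing silence.
#'
#' @param prototype a single prototype from [call_prototypes()], or any list
#'   with \code{f_start}, \code{f_end}, \code{tonal_fraction},
#'   \code{dur_mean}.
#' @param sample_rate sampling rate in Hz; must exceed twice the highest
#'   synthesized frequency.
#' @param dur call duration in seconds (default the prototype mean).
#' @param seed integer seed controlling noise and harmonic phases.
#' @param pad silence in seconds added before and after the call.
#' @param n_harmonics number of harmonics in the tonal stack; harmonics
#'   reaching above 0.95 Nyquist are dropped.
#' @return list with \code{wave}, \code{sample_rate}, \code{start},
#'   \code{end} (call bounds in seconds within the padded waveform) and
#'   \code{label}.
#' @export
synth_call_wave <- function(prototype, sample_rate = 44100, dur = NULL,
                            seed = 1, pad = 0.05, n_harmonics = 5) {
  f0 <- c(prototype$f_start, prototype$f_end)
  tf <- prototype$tonal_fraction
  if (is.null(dur)) dur <- prototype$dur_mean
  if (!is.numeric(dur) || dur <= 0) stop("call duration must be positive")
  if (dur < 0.034) stop("call duration below the 34 ms analysis minimum")
  if (tf < 0 || tf > 1) stop("tonal_fraction must be in [0, 1]")
  if (max(f0) * 2 >= sample_rate)
    stop("fundamental frequency ", max(f0), " Hz exceeds Nyquist of ",
         sample_rate / 2, " Hz")
  with_seed(seed, {
    n <- max(2L, round(dur * sample_rate))
    t_rel <- (seq_len(n) - 1) / sample_rate
    finst <- f0[1] + (f0[2] - f0[1]) * t_rel / dur
    phase <- 2 * pi * cumsum(finst) / sample_rate
    tonal <- numeric(n)
    for (h in seq_len(n_harmonics)) {
      if (h * max(f0) >= 0.95 * sample_rate / 2) break
      tonal <- tonal + sin(h * phase + stats::runif(1, 0, 2 * pi)) / h
    }
    noise <- stats::rnorm(n)
    unit <- function(x) {
      r <- sqrt(mean(x^2))
      if (r > 0) x / r else x
    }
    wave <- sqrt(tf) * unit(tonal) + sqrt(1 - tf) * unit(noise)
    # raised-cosine edge taper
    nt <- max(2L, min(round(0.005 * sample_rate), floor(n / 4)))
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nt) - 1) / (nt - 1)))
    wave[seq_len(nt)] <- wave[seq_len(nt)] * ramp
    wave[n - nt + seq_len(nt)] <- wave[n - nt + seq_len(nt)] * rev(ramp)
    wave <- wave / max(abs(wave)) * 0.9
    npad <- round(pad * sample_rate)
    list(wave = c(numeric(npad), wave, numeric(npad)),
         sample_rate = sample_rate,
         start = npad / sample_rate,
         end = (npad + n) / sample_rate,
         label = prototype$label %||% "call")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an expert valence-ranking table
#'
#' Each simulated expert ranks the situations by negativity. Starting from
#' the true ordering, one pass of adjacent transpositions is applied, each
#' pair being swapped independently with probability \code{swap_noise}, so
#' \code{swap_noise = 0} reproduces the true order exactly.
#'
#' @param true_order character vector of situation codes ordered from most
#'   negative (rank 1) to most positive.
#' @param n_experts number of experts (rows).
#' @param swap_noise per-pair swap probability in [0, 1].
#' @param seed integer seed.
#' @return integer matrix \code{n_experts} x \code{length(true_order)};
#'   columns named by situation, each row a permutation of 1..S giving that
#'   expert's negativity ranks.
#' @export
simulate_expert_ranks <- function(true_order, n_experts = 28,
                                  swap_noise = 0.2, seed = 1) {
  stopifnot(n_experts >= 1)
  if (swap_noise < 0 || swap_noise > 1)
    stop("swap_noise must be in [0, 1]")
  s <- length(true_order)
  if (anyDuplicated(true_order)) stop("true_order has duplicates")
  with_seed(seed, {
    out <- matrix(0L, n_experts, s, dimnames = list(NULL, sort(true_order)))
    for (e in seq_len(n_experts)) {
      ord <- true_order
      for (i in sample(seq_len(s - 1))) {
        if (stats::runif(1) < swap_noise) ord[c(i, i + 1)] <- ord[c(i + 1, i)]
      }
      out[e, ord] <- seq_len(s)
    }
    out
  })
}

#' Mean expert valence rank per situation
#'
#' Averages the negativity ranks over experts (rank 1 = most negative) and
#' attaches a normal-approximation 95 percent confidence interval.
#'
#' @param ranks expert-by-situation rank matrix from
#'   [simulate_expert_ranks()] or an equivalent survey table; every row must
#'   be a permutation of 1..S.
#' @return data.frame with columns \code{situation}, \code{mean_rank},
#'   \code{ci_lo}, \code{ci_hi}, ordered by increasing mean rank.
#' @export
mean_valence <- function(ranks) {
  ranks <- as.matrix(ranks)
  s <- ncol(ranks)
  if (is.null(colnames(ranks))) colnames(ranks) <- paste0("S", seq_len(s))
  ok <- apply(ranks, 1, function(r) setequal(r, seq_len(s)))
  if (!all(ok))
    stop("row(s) ", paste(which(!ok), collapse = ", "),
         " are not permutations of 1..", s)
  m <- colMeans(ranks)
  se <- apply(ranks, 2, stats::sd) / sqrt(nrow(ranks))
  out <- data.frame(situation = colnames(ranks), mean_rank = m,
                    ci_lo = m - stats::qnorm(0.975) * se,
                    ci_hi = m + stats::qnorm(0.975) * se,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$mean_rank), ]
}
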