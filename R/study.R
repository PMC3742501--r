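#' Situation metadata for the piglet recording study
#'
#' Returns the packaged description of the eleven recording situations used
#' throughout the package as the default study design: situation code,
#' a short tag, the gross biological category, and the number of analysed
#' calls, recorded piglets and litters per situation.
#'
#' @return A data.frame with 11 rows and columns \code{situation},
#'   \code{tag}, \code{gross}, \code{n_calls}, \code{n_piglets},
#'   \code{n_litters}.
#' @examples
#' sit <- piglet_situations()
#' sum(sit$n_calls)   # 1513 calls in total
#' table(sit$gross)   # three gross categories
#' @export
piglet_situations <- function() {
  out <- data.frame(
    situation = c("CA", "CR", "AR", "FI", "BN", "AN", "MN",
                  "HU", "IS", "RE", "SU"),
    tag = c("castration", "crushing", "arms_of_person", "fighting",
            "before_nursing", "after_nursing", "missed_nursing",
            "huddling", "isolation", "reunion", "surprise"),
    n_calls   = c(171L, 159L, 209L, 115L, 61L, 128L, 70L,
                  81L, 222L, 279L, 18L),
    n_piglets = c(7L, 10L, 6L, 5L, 5L, 14L, 6L, 10L, 5L, 15L, 10L),
    n_litters = c(5L, 10L, 4L, 4L, 5L, 9L, 4L, 3L, 5L, 5L, 6L),
    stringsAsFactors = FALSE
  )
  out$gross <- gross_category(out$situation)
  out[, c("situation", "tag", "gross", "n_calls", "n_piglets", "n_litters")]
}

#' Collapse situation codes to their gross biological category
#'
#' Maps the eleven situation codes onto the three-way grouping used for
#' coarse classification: life-threatening (CA, CR, AR, FI), nursing-related
#' (BN, AN, MN) and general social (HU, IS, RE, SU) situations.
#'
#' @param situation character vector of situation codes.
#' @return character vector of \code{"life_threat"}, \code{"nursing"} or
#'   \code{"other"}, same length as \code{situation}.
#' @examples
#' gross_category(c("CA", "MN", "RE"))
#' @export
gross_category <- function(situation) {
  map <- c(CA = "life_threat", CR = "life_threat", AR = "life_threat",
           FI = "life_threat",
           BN = "nursing", AN = "nursing", MN = "nursing",
           HU = "other", IS = "other", RE = "other", SU = "other")
  situation <- as.character(situation)
  bad <- setdiff(unique(situation), names(map))
  if (length(bad))
    stop("unknown situation code(s): ", paste(bad, collapse = ", "),
         "; valid codes are ", paste(names(map), collapse = ", "))
  unname(map[situation])
}
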