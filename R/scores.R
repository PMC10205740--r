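# The two damage scores.
#
# S_nuclei = N_dmg / N_all is the classical pathologist score: the fraction
# of damaged nuclei among all nuclei visible in the epidermis. S_area =
# A_dmg / A_epi is the area-based score derived from a three-class
# segmentation: damaged-epidermis pixels over all epidermis pixels, where
# damaged pixels count as epidermis (damage lies within the epidermis), so
# S_area <= 1 by construction.

#' Nuclei counts underlying the S_nuclei score
#'
#' @param n_dmg Number of damaged nuclei (non-negative integer).
#' @param n_all Total number of nuclei (positive integer, `>= n_dmg`).
#' @return A list of class `epiderm_nuclei_counts`.
#' @export
nuclei_counts <- function(n_dmg, n_all) {
  if (!is_count(n_dmg) || n_dmg < 0) stop("n_dmg must be a non-negative integer")
  if (!is_count(n_all) || n_all < 0) stop("n_all must be a non-negative integer")
  if (n_dmg > n_all) stop("n_dmg must not exceed n_all")
  structure(list(n_dmg = as.integer(n_dmg), n_all = as.integer(n_all)),
            class = "epiderm_nuclei_counts")
}

#' A pair of per-sample damage scores
#'
#' At least one of `s_nuclei`, `s_area` must be present; each lies in
#' `[0, 1]`.
#'
#' @param s_nuclei,s_area Optional fractions.
#' @return A list of class `epiderm_score_pair`.
#' @export
score_pair <- function(s_nuclei = NULL, s_area = NULL) {
  if (is.null(s_nuclei) && is.null(s_area))
    ep_stop("at least one of s_nuclei, s_area must be present",
            "epiderm_validation_error")
  for (s in c(s_nuclei, s_area))
    if (!is.finite(s) || s < 0 || s > 1)
      ep_stop("scores must lie in [0, 1]", "epiderm_validation_error")
  structure(list(s_nuclei = s_nuclei, s_area = s_area),
            class = "epiderm_score_pair")
}

#' Relative damaged-nuclei count S_nuclei
#'
#' @param counts An [nuclei_counts()] object (or a list with `n_dmg`, `n_all`).
#' @return `n_dmg / n_all`.
#' @export
s_nuclei_from_counts <- function(counts) {
  if (counts$n_all < 1)
    ep_stop("S_nuclei is undefined for n_all = 0", "epiderm_undefined_score")
  counts$n_dmg / counts$n_all
}

#' Relative damaged area S_area from a label mask
#'
#' `A_dmg` is the number of damaged-epidermis pixels (class 2); `A_epi`
#' counts all epidermis pixels, healthy or damaged (classes 1 and 2).
#' A mask without any epidermis raises an `epiderm_undefined_score` error
#' rather than returning 0: a failed epidermis detection must stay visible.
#'
#' @param mask Integer matrix with classes in `{0, 1, 2}`.
#' @return A list with `s_area`, `a_dmg` and `a_epi` (pixel counts).
#' @export
s_area_from_mask <- function(mask) {
  vals <- unique(c(mask))
  if (!all(vals %in% 0:2))
    ep_stop(paste0("unknown mask value ", setdiff(vals, 0:2)[1]), "epiderm_mask_error")
  a_dmg <- sum(mask == 2L)
  a_epi <- a_dmg + sum(mask == 1L)
  if (a_epi == 0)
    ep_stop("S_area is undefined: mask contains no epidermis", "epiderm_undefined_score")
  list(s_area = a_dmg / a_epi, a_dmg = a_dmg, a_epi = a_epi)
}

#' Convert between score kinds
#'
#' The two scores live on the same `[0, 1]` scale and correlate strongly,
#' so the conversion used for cross-score comparison is the identity: the
#' available score is used directly as the estimate of the other. When the
#' requested score is itself present it is returned unchanged.
#'
#' @param pair An [score_pair()].
#' @param target `"nuclei"` or `"area"`.
#' @return A fraction in `[0, 1]`.
#' @export
cross_score <- function(pair, target = c("nuclei", "area")) {
  target <- match.arg(target)
  own <- if (target == "nuclei") pair$s_nuclei else pair$s_area
  if (!is.null(own)) return(own)
  other <- if (target == "nuclei") pair$s_area else pair$s_nuclei
  if (is.null(other))
    ep_stop("score pair holds neither score", "epiderm_validation_error")
  other
}
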