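#' Classify clinal alleles by evidence-ratio percentile
#'
#' Rather than an arbitrary evidence-ratio cutoff, a locus is called clinal
#' when its evidence ratio (best cline model vs the uniform null) strictly
#' exceeds the empirical 99th percentile of the genome-wide distribution
#' over converged fits (linear interpolation). Non-converged loci are never
#' clinal.
#'
#' @param clines Per-locus tibble from [fit_clines()].
#' @param percentile Percentile defining the threshold (default 0.99).
#' @return The input with columns `is_clinal` and `threshold_used` added.
#' @export
classify_clinal <- function(clines, percentile = 0.99) {
  conv <- clines$converged & is.finite(clines$evidence_ratio)
  if (!any(conv)) {
    warning("no converged cline fits; no locus can be classified clinal",
            call. = FALSE)
    return(dplyr::mutate(clines, is_clinal = FALSE,
                         threshold_used = NA_real_))
  }
  if (sum(conv) < 100) {
    warning("fewer than 100 converged fits; the ",
            round(100 * percentile),
            "th-percentile threshold is unreliable", call. = FALSE)
  }
  threshold <- unname(quantile(clines$evidence_ratio[conv], percentile,
                               type = 7))
  dplyr::mutate(clines,
                is_clinal = conv & .data$evidence_ratio > threshold,
                threshold_used = threshold)
}

#' Frequency-matched background for enrichment tests
#'
#' For each candidate locus, all fitted loci whose fitted end-frequency
#' difference `delta_p` falls in the same bin (default width 0.05) form the
#' matched background; the background of a candidate set is the union over
#' its candidates (no double counting).
#'
#' @param candidates Character vector of candidate `locus_id`s.
#' @param calls Classified tibble from [classify_clinal()] (needs
#'   `locus_id`, `delta_p`).
#' @param bin_width Width of the `delta_p` matching bins (default 0.05).
#' @return Character vector of background `locus_id`s (includes the
#'   candidates themselves).
#' @export
matched_background <- function(candidates, calls, bin_width = 0.05) {
  known <- candidates %in% calls$locus_id
  if (!all(known)) {
    warning(sum(!known), " candidate(s) absent from fitted loci dropped",
            call. = FALSE)
    candidates <- candidates[known]
  }
  breaks <- seq(0, 1, by = bin_width)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  bin_of <- function(dp) findInterval(dp, breaks, rightmost.closed = TRUE)
  calls_ok <- dplyr::filter(calls, !is.na(.data$delta_p))
  cand_bins <- unique(bin_of(
    calls_ok$delta_p[match(candidates, calls_ok$locus_id)]))
  cand_bins <- cand_bins[!is.na(cand_bins)]
  calls_ok$locus_id[bin_of(calls_ok$delta_p) %in% cand_bins]
}

#' Hypergeometric enrichment of candidate sets for clinal alleles
#'
#' Upper-tail hypergeometric test of whether a candidate-SNP set contains
#' more clinal alleles than expected from a background matched on the
#' fitted end-frequency difference. P-values are Bonferroni-adjusted across
#' the sets tested in one call.
#'
#' @param candidate_sets Named list of character vectors of `locus_id`s
#'   (e.g., genome-scan and GEA candidate lists), or a single character
#'   vector.
#' @param calls Classified tibble from [classify_clinal()].
#' @param bin_width Passed to [matched_background()].
#' @return Tibble with one row per set: counts, `p_value`, `p_adjusted`.
#' @export
enrichment_test <- function(candidate_sets, calls, bin_width = 0.05) {
  if (!is.list(candidate_sets)) {
    candidate_sets <- list(candidates = candidate_sets)
  }
  if (is.null(names(candidate_sets))) {
    names(candidate_sets) <- paste0("set", seq_along(candidate_sets))
  }
  res <- purrr::imap_dfr(candidate_sets, function(cand, set_id) {
    cand <- intersect(cand, calls$locus_id)
    if (length(cand) == 0) {
      stop("candidate set '", set_id, "' has no fitted locus",
           call. = FALSE)
    }
    bg <- matched_background(cand, calls, bin_width = bin_width)
    is_cl <- calls$is_clinal[match(bg, calls$locus_id)]
    N <- length(bg)
    K <- sum(is_cl)
    n_cand <- length(cand)
    obs <- sum(calls$is_clinal[match(cand, calls$locus_id)])
    p <- phyper(obs - 1, K, N - K, n_cand, lower.tail = FALSE)
    tibble::tibble(candidate_set_id = set_id, n_background = N,
                   n_background_clinal = K, n_candidates = n_cand,
                   n_candidates_clinal = obs, p_value = p)
  })
  dplyr::mutate(res, p_adjusted = p.adjust(.data$p_value,
                                           method = "bonferroni"))
}

#' Selection coefficient from cline width and neighbourhood size
#'
#' Under migration-selection balance the cline width scales as
#' `w ~ sigma / sqrt(s)`; with neighbourhood size N_S as proxy for the
#' dispersal variance sigma^2 this gives `s = N_S / w^2`.
#'
#' @param n_s Neighbourhood size (positive scalar), typically
#'   `ibd_regression(...)$n_s`.
#' @param width Cline width(s), km.
#' @return Numeric vector of selection intensities (NA where `n_s` is
#'   undefined or `width` missing/non-positive).
#' @export
#' @examples
#' selection_coefficient(200, 100)  # 0.02
selection_coefficient <- function(n_s, width) {
  if (is.na(n_s) || length(n_s) != 1) {
    warning("neighbourhood size undefined; selection coefficients are NA",
            call. = FALSE)
    return(rep(NA_real_, length(width)))
  }
  if (n_s <= 0) stop("n_s must be > 0", call. = FALSE)
  out <- rep(NA_real_, length(width))
  ok <- !is.na(width) & width > 0
  out[ok] <- n_s / width[ok]^2
  out
}

#' Per-locus selection coefficients for clinal selection candidates
#'
#' Applies [selection_coefficient()] to the fitted widths of loci that are
#' both clinal and in a candidate set.
#'
#' @param calls Classified tibble from [classify_clinal()].
#' @param ibd An `ibd_fit` object (supplies N_S).
#' @param candidates Optional character vector restricting loci; default
#'   all clinal loci.
#' @return Tibble `locus_id`, `best_model`, `width`, `n_s`, `s`.
#' @export
selection_estimates <- function(calls, ibd, candidates = NULL) {
  keep <- calls$is_clinal
  if (!is.null(candidates)) keep <- keep & calls$locus_id %in% candidates
  sel <- calls[keep, c("locus_id", "best_model", "width")]
  if (!isTRUE(ibd$n_s_defined)) {
    warning("IBD slope non-positive: N_S undefined, all s reported NA",
            call. = FALSE)
    return(dplyr::mutate(sel, n_s = NA_real_, s = NA_real_,
                         status = "n_s_undefined"))
  }
  dplyr::mutate(sel, n_s = ibd$n_s,
                s = selection_coefficient(ibd$n_s, .data$width),
                status = "ok")
}
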