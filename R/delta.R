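# Bounded combinatorial explanation of intact-mass differences.

# combinations with repetition of 1..n taken k at a time, as a matrix with
# k columns (one row per multiset); k = 0 yields a single empty multiset
multisets <- function(n, k) {
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  if (n == 1) return(matrix(rep(1L, k), nrow = 1))
  m <- utils::combn(n + k - 1, k)
  t(m - (seq_len(k) - 1L))
}

#' Explain an observed mass difference with catalog entries
#'
#' Exhaustively enumerates multisets of catalog entries of size up to
#' `k_max` and returns those whose net average-mass shift matches the
#' observed difference within `tol`, ranked by parsimony first (fewer
#' entries), then absolute residual, then name. Deterministic. The empty
#' multiset explains a difference within `tol` of zero.
#'
#' When a [proteoform()] is supplied, sequence-aware N-terminal truncation
#' entries generated from its actual sequence (up to `trunc_max` residues)
#' are added to the catalog, so a truncated proteoform is explained by the
#' loss of its own residues rather than a generic average.
#'
#' @param delta Observed mass difference in Da (observed minus theoretical).
#' @param catalog A [read_catalog()] data.frame.
#' @param k_max Maximum multiset size; values above 4 are refused unless
#'   `allow_large_k = TRUE` (combinatorial guard).
#' @param tol Mass tolerance in Da (`> 0`; default 1.5, the scale tolerated
#'   by intact-mass assignments at 28-99 kDa).
#' @param proteoform Optional [proteoform()] enabling sequence-aware
#'   truncations.
#' @param trunc_max Longest sequence-aware truncation added.
#' @param allow_large_k Override the `k_max <= 4` guard.
#' @return data.frame of class `delta_explanations` with columns `entries`
#'   (names joined by `+`, `"(none)"` for the empty set), `net_shift`,
#'   `residual` (`delta - net_shift`), `cardinality`.
#' @examples
#' explain_delta(61.5)   # top explanation: one Cu(II)
#' explain_delta(-89.1, tol = 1)  # Met_OFF + NtAc
#' @export
explain_delta <- function(delta, catalog = read_catalog(), k_max = 3,
                          tol = 1.5, proteoform = NULL, trunc_max = 10,
                          allow_large_k = FALSE) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (k_max > 4 && !allow_large_k) {
    stop("k_max > 4 refused (combinatorial guard); ",
         "set allow_large_k = TRUE to override", call. = FALSE)
  }
  if (!nrow(catalog)) stop("catalog is empty", call. = FALSE)
  if (!is.null(proteoform)) {
    catalog <- rbind(as.data.frame(catalog),
                     as.data.frame(truncation_entries(proteoform$sequence,
                                                      trunc_max)))
  }
  shifts <- catalog$net_average
  n <- nrow(catalog)
  res <- list()
  for (k in 0:k_max) {
    comb <- multisets(n, k)
    net <- if (k == 0) 0 else {
      if (k == 1) shifts[comb[, 1]] else rowSums(matrix(shifts[comb], ncol = k))
    }
    ok <- abs(delta - net) <= tol
    if (!any(ok)) next
    comb <- comb[ok, , drop = FALSE]
    labels <- if (k == 0) "(none)" else
      apply(comb, 1, function(ix) paste(sort(catalog$name[ix]), collapse = "+"))
    res[[length(res) + 1]] <- data.frame(entries = labels,
                                         net_shift = net[ok],
                                         residual = delta - net[ok],
                                         cardinality = k)
  }
  if (!length(res)) {
    out <- data.frame(entries = character(0), net_shift = numeric(0),
                      residual = numeric(0), cardinality = integer(0))
  } else {
    out <- do.call(rbind, res)
    out <- out[order(out$cardinality, abs(out$residual), out$entries), ]
    rownames(out) <- NULL
  }
  class(out) <- c("delta_explanations", "data.frame")
  out
}
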