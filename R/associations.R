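#' Select intestinal-clock-controlled taxa
#'
#' Taxa that are rhythmic in the control group but not in the second group
#' (categories `loss` and `trend_loss` of [compare_rhythms()]) and detected
#' in at least `prevalence_min` of the samples of the relative-abundance
#' table.
#'
#' @param diff a [compare_rhythms()] result.
#' @param rel relative abundance matrix used for prevalence.
#' @param prevalence_min detection prevalence threshold, default 0.30.
#' @return character vector of taxon ids (possibly empty, with a warning).
#' @export
select_clock_controlled <- function(diff, rel, prevalence_min = 0.30) {
  cand <- diff$taxon[diff$category %in% c("loss", "trend_loss")]
  cand <- intersect(cand, colnames(rel))
  prev <- colMeans(rel[, cand, drop = FALSE] > 0)
  keep <- cand[prev >= prevalence_min]
  if (length(keep) == 0)
    warning("no clock-controlled taxa pass the prevalence filter")
  keep
}

# Spearman rho with midranks plus the t-approximation p-value, vectorized
# over the columns of two matrices with pairwise-complete observations.
spearman_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4) return(c(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = sign(rho), p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  c(rho = rho, p = p, n = n)
}

#' Thresholded Spearman taxon-metabolite correlation
#'
#' Spearman rank correlation (midranks for ties, pairwise-complete
#' observations) between every taxon column and every metabolite column,
#' with the t-approximation p-value, Benjamini-Hochberg adjustment over the
#' full matrix, and the conventional report mask: raw p <= `p_max` and
#' |rho| >= `rho_min`.
#'
#' @param taxa_table samples x taxa matrix (e.g. relative abundance of
#'   clock-controlled taxa).
#' @param metabolites samples x metabolites matrix (missing values allowed).
#' @param p_max raw p-value threshold for the mask, default 0.05.
#' @param rho_min absolute-correlation threshold for the mask, default 0.5.
#' @return An object of class `correlation_result`: list with matrices `rho`,
#'   `p`, `adj_p`, logical `mask`, and `pairs` (long-format data.frame of
#'   masked pairs).
#' @export
spearman_matrix <- function(taxa_table, metabolites, p_max = 0.05,
                            rho_min = 0.5) {
  common <- intersect(rownames(taxa_table), rownames(metabolites))
  if (length(common) < 4)
    abort_located("need >= 4 shared samples (have ", length(common), ")")
  tx <- taxa_table[common, , drop = FALSE]
  mb <- metabolites[common, , drop = FALSE]
  nt <- ncol(tx); nm <- ncol(mb)
  rho <- p <- matrix(NA_real_, nt, nm,
                     dimnames = list(colnames(tx), colnames(mb)))
  for (i in seq_len(nt)) {
    for (j in seq_len(nm)) {
      r <- spearman_pair(tx[, i], mb[, j])
      rho[i, j] <- r["rho"]; p[i, j] <- r["p"]
    }
  }
  adj_p <- matrix(stats::p.adjust(as.vector(p), method = "BH"), nt, nm,
                  dimnames = dimnames(p))
  mask <- !is.na(p) & p <= p_max & abs(rho) >= rho_min
  idx <- which(mask, arr.ind = TRUE)
  pairs <- data.frame(taxon = rownames(rho)[idx[, 1]],
                      metabolite = colnames(rho)[idx[, 2]],
                      rho = rho[mask], p = p[mask], adj_p = adj_p[mask],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$p, pairs$taxon, pairs$metabolite), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(rho = rho, p = p, adj_p = adj_p, mask = mask, pairs = pairs),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Spearman correlation:", nrow(x$rho), "taxa x", ncol(x$rho),
      "metabolites;", sum(x$mask, na.rm = TRUE), "masked pair(s)\n")
  invisible(x)
}
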