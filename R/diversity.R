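#' Alpha diversity: richness and Shannon effective number of species
#'
#' Richness is the count of detected taxa (abundance > 0); the Shannon
#' effective number of species is exp(H) with H = -sum p log p over positive
#' fractions, i.e. diversity in units of equally-abundant taxa.
#'
#' @param rel relative abundance matrix (samples x taxa, rows sum to 1).
#' @return data.frame with `sample_id`, `richness`, `shannon_effective`.
#' @export
alpha_diversity <- function(rel) {
  if (nrow(rel) == 0) abort_located("empty abundance table")
  if (any(rowSums(rel) == 0)) abort_located("sample with no detected taxa")
  richness <- rowSums(rel > 0)
  H <- apply(rel, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  data.frame(sample_id = rownames(rel), richness = as.integer(richness),
             shannon_effective = exp(H), stringsAsFactors = FALSE,
             row.names = rownames(rel))
}

# samples x edges matrix of cumulative branch proportions: entry (s, e) is the
# summed abundance over the leaves descending from edge e.
branch_proportions <- function(rel, tree) {
  missing_taxa <- setdiff(colnames(rel), tree$tip.label)
  if (length(missing_taxa) > 0)
    abort_located("taxa missing from tree: ",
                  paste(utils::head(missing_taxa, 5), collapse = ", "),
                  if (length(missing_taxa) > 5) ", ..." else "")
  if (any(tree$edge.length < 0)) abort_located("tree has negative branch lengths")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  # accumulate abundances from tips up through internal nodes (postorder)
  node_ab <- matrix(0, nrow = nrow(rel), ncol = n_tip + n_node)
  idx <- match(tree$tip.label, colnames(rel))
  have <- !is.na(idx)
  node_ab[, which(have)] <- as.matrix(rel[, idx[have], drop = FALSE])
  edge_order <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge_order))) {
    parent <- edge_order[k, 1]; child <- edge_order[k, 2]
    node_ab[, parent] <- node_ab[, parent] + node_ab[, child]
  }
  P <- node_ab[, tree$edge[, 2], drop = FALSE]
  rownames(P) <- rownames(rel)
  P
}

#' Generalized UniFrac distance matrix
#'
#' d(A, B) = sum_b L_b (p_Ab + p_Bb)^alpha |p_Ab - p_Bb| / (p_Ab + p_Bb)
#'           / sum_b L_b (p_Ab + p_Bb)^alpha
#' where p_.b is the summed relative abundance of the leaves under branch b
#' and L_b the branch length; branches with p_Ab + p_Bb = 0 are skipped.
#' alpha = 1 is weighted UniFrac (normalized); alpha = 0.5 moderates the
#' weight of highly abundant lineages and is the default.
#'
#' @param rel relative abundance matrix (samples x taxa, rows sum to 1).
#' @param tree rooted `phylo` tree containing every taxon as a leaf.
#' @param alpha abundance-weighting exponent in \[0, 1\], default 0.5.
#' @return symmetric distance matrix with zero diagonal, entries in \[0, 1\].
#' @export
gunifrac <- function(rel, tree, alpha = 0.5) {
  P <- branch_proportions(rel, tree)
  L <- tree$edge.length
  n <- nrow(P)
  D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n - 1)) {
    pi_ <- P[i, ]
    for (j in (i + 1):n) {
      pj <- P[j, ]
      s <- pi_ + pj
      use <- s > 0
      wt <- L[use] * s[use]^alpha
      num <- sum(wt * abs(pi_[use] - pj[use]) / s[use])
      den <- sum(wt)
      D[i, j] <- D[j, i] <- if (den > 0) num / den else 0
    }
  }
  D
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance of a distance matrix
#' against a grouping factor (pseudo-F from the distance-based partition of
#' sums of squares; \pkg{vegan}'s `adonis2` engine). Optionally runs all
#' pairwise two-group tests with Bonferroni adjustment.
#'
#' @param dist distance matrix (square symmetric or `dist`).
#' @param labels grouping vector, one per sample.
#' @param n_perm number of permutations, default 999.
#' @param seed RNG seed for the permutations.
#' @param pairwise also test all group pairs, default FALSE.
#' @return list with `pseudo_f`, `r2`, `p_perm`, `n_perm`, and when requested
#'   `pairwise` (data.frame with Bonferroni-adjusted p-values).
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = NULL,
                      pairwise = FALSE) {
  d <- stats::as.dist(dist)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) abort_located("need >= 2 groups")
  if (any(table(labels) < 2)) abort_located("singleton group in labels")
  run <- function(dd, ll) {
    df <- data.frame(grp = ll)
    fit <- vegan::adonis2(dd ~ grp, data = df, permutations = n_perm)
    list(pseudo_f = fit$F[1], r2 = fit$R2[1], p_perm = fit$`Pr(>F)`[1])
  }
  main <- if (is.null(seed)) run(d, labels) else with_seed(seed, run(d, labels))
  out <- c(main, list(n_perm = n_perm))
  if (pairwise) {
    dm <- as.matrix(d)
    prs <- utils::combn(levels(labels), 2, simplify = FALSE)
    tab <- do.call(rbind, lapply(seq_along(prs), function(k) {
      pr <- prs[[k]]
      sel <- labels %in% pr
      sub <- stats::as.dist(dm[sel, sel])
      r <- if (is.null(seed)) run(sub, droplevels(labels[sel])) else
        with_seed(derive_seed(seed, paste(pr, collapse = "_")),
                  run(sub, droplevels(labels[sel])))
      data.frame(group_1 = pr[1], group_2 = pr[2], pseudo_f = r$pseudo_f,
                 r2 = r$r2, p_perm = r$p_perm, stringsAsFactors = FALSE)
    }))
    tab$p_adj <- stats::p.adjust(tab$p_perm, method = "bonferroni")
    out$pairwise <- tab
  }
  out
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigen-decomposition of the double-centered squared distance matrix;
#' negative eigenvalues are dropped with a warning and axes are ordered by
#' eigenvalue.
#'
#' @param dist distance matrix.
#' @param k number of axes, default 2.
#' @return list with `coords` (samples x k), `explained` (fraction of the
#'   positive eigenvalue sum per axis) and `eig`.
#' @export
pcoa <- function(dist, k = 2) {
  d <- as.matrix(stats::as.dist(dist))
  fit <- stats::cmdscale(d, k = min(k, nrow(d) - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  if (any(fit$eig < -1e-8))
    warning("pcoa: ", sum(fit$eig < -1e-8),
            " negative eigenvalue(s) dropped (non-Euclidean distances)")
  if (k > length(pos))
    abort_located("k = ", k, " exceeds the number of positive eigenvalues (",
                  length(pos), ")")
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("axis_", seq_len(k))
  list(coords = coords, explained = fit$eig[seq_len(k)] / sum(pos),
       eig = fit$eig)
}

#' Per-sample distance to a reference time point
#'
#' Quantifies beta-diversity time courses: for every sample, the mean
#' distance to all samples taken at the reference time (the sample itself is
#' excluded when it belongs to the reference set), followed by a per-group
#' cosinor fit of distance versus time.
#'
#' @param dist distance matrix over samples.
#' @param meta metadata with `sample_id`, `time_h`, `group`.
#' @param ref_time_h reference time (hours), default 1 (i.e. ZT1/CT1).
#' @return list with `distances` (data.frame: sample_id, time_h, group,
#'   dist_to_ref) and `fits` (per-group `cosinor_fit`).
#' @export
distance_to_reference <- function(dist, meta, ref_time_h = 1) {
  dm <- as.matrix(dist)
  meta <- meta[match(rownames(dm), meta$sample_id), , drop = FALSE]
  ref <- meta$sample_id[abs(meta$time_h - ref_time_h) < 1e-9]
  if (length(ref) == 0)
    abort_located("no samples at reference time ", ref_time_h, " h")
  d2r <- vapply(rownames(dm), function(s) {
    others <- setdiff(ref, s)
    if (length(others) == 0) return(NA_real_)
    mean(dm[s, others])
  }, numeric(1))
  res <- data.frame(sample_id = rownames(dm), time_h = meta$time_h,
                    group = meta$group, dist_to_ref = d2r,
                    stringsAsFactors = FALSE)
  fits <- lapply(split(res, res$group), function(df) {
    ok <- is.finite(df$dist_to_ref)
    if (sum(ok) >= 4 && length(unique(df$time_h[ok])) >= 3)
      fit_cosinor(df$time_h[ok], df$dist_to_ref[ok]) else NULL
  })
  list(distances = res, fits = fits)
}

#' Procrustes comparison of two ordinations
#'
#' Optimal translation/rotation/uniform-scaling superimposition of
#' configuration B onto A; `m2` is the symmetric normalized residual
#' sum-of-squares and the p-value comes from the PROTEST permutation of
#' sample identities (\pkg{vegan} engine). Reflections are allowed by
#' default (the orthogonal Procrustes solution); set `allow_reflection =
#' FALSE` to restrict to pure rotations.
#'
#' @param coords_a,coords_b samples x k coordinate matrices with matching
#'   (named) samples.
#' @param n_perm permutations for PROTEST, default 999.
#' @param seed RNG seed.
#' @param allow_reflection allow improper rotations, default TRUE.
#' @return list with `m2`, `correlation` (sqrt(1 - m2)), `p_perm`, `n_perm`.
#' @export
procrustes_fit <- function(coords_a, coords_b, n_perm = 999, seed = NULL,
                           allow_reflection = TRUE) {
  if (!is.null(rownames(coords_a)) && !is.null(rownames(coords_b))) {
    if (!setequal(rownames(coords_a), rownames(coords_b)))
      abort_located("sample sets of the two configurations differ")
    coords_b <- coords_b[rownames(coords_a), , drop = FALSE]
  } else if (nrow(coords_a) != nrow(coords_b)) {
    abort_located("configurations have different numbers of samples")
  }
  if (!allow_reflection) {
    # vegan's SVD rotation permits reflection; fall back to a det-corrected
    # rotation and a manual permutation test in the rotation-only case
    m2_rot <- function(A, B) {
      A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
      A <- A / sqrt(sum(A^2)); B <- B / sqrt(sum(B^2))
      s <- svd(crossprod(A, B))
      d <- rep(1, length(s$d));
      if (det(s$v %*% t(s$u)) < 0) d[length(d)] <- -1
      1 - sum(s$d * d)^2
    }
    m2 <- m2_rot(coords_a, coords_b)
    perm_fun <- function() {
      stat <- vapply(seq_len(n_perm), function(i)
        m2_rot(coords_a[sample(nrow(coords_a)), , drop = FALSE], coords_b),
        numeric(1))
      (1 + sum(stat <= m2)) / (1 + n_perm)
    }
    p <- if (is.null(seed)) perm_fun() else with_seed(seed, perm_fun())
    return(list(m2 = m2, correlation = sqrt(max(0, 1 - m2)), p_perm = p,
                n_perm = n_perm))
  }
  run <- function() vegan::protest(coords_a, coords_b, permutations = n_perm)
  pt <- if (is.null(seed)) run() else with_seed(seed, run())
  list(m2 = pt$ss, correlation = pt$t0, p_perm = pt$signif, n_perm = n_perm)
}
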