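test_that("alpha diversity matches hand-computed values", {
  rel <- rbind(uniform = rep(0.25, 4),
               single = c(1, 0, 0, 0),
               skew = c(0.5, 0.25, 0.25, 0))
  colnames(rel) <- paste0("t", 1:4)
  a <- alpha_diversity(rel)
  expect_equal(a$richness, c(4L, 1L, 3L))
  # uniform over k taxa -> effective number k; single taxon -> 1
  # H(0.5, 0.25, 0.25) = 1.5 * log(2) -> exp = 2^1.5
  expect_equal(a$shannon_effective, c(4, 1, 2^1.5), tolerance = 1e-12)
})

test_that("gunifrac matches closed forms on hand-built trees", {
  # star tree, unit branches, disjoint single-leaf samples -> distance 1
  star <- ape::read.tree(text = "(A:1,B:1,C:1):0;")
  rel <- rbind(s1 = c(A = 1, B = 0, C = 0), s2 = c(A = 0, B = 1, C = 0))
  D <- gunifrac(rel, star, alpha = 0.5)
  expect_equal(D["s1", "s2"], 1)
  expect_equal(diag(D), c(s1 = 0, s2 = 0))
  # identical samples -> 0
  expect_equal(gunifrac(rel[c(1, 1), ], star)[1, 2], 0)

  # 5-leaf tree, alpha = 1: hand-computed weighted-UniFrac oracle.
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1,(D:2,E:1):1):2):0;")
  p1 <- c(A = 0.1, B = 0.2, C = 0.3, D = 0.25, E = 0.15)
  p2 <- c(A = 0.3, B = 0.1, C = 0.05, D = 0.05, E = 0.5)
  # branches enumerated manually: (length, descendant set)
  branches <- list(list(1, "A"), list(2, "B"), list(1, c("A", "B")),
                   list(1, "C"), list(2, "D"), list(1, "E"),
                   list(1, c("D", "E")), list(2, c("C", "D", "E")))
  num <- sum(sapply(branches, function(b) b[[1]] * abs(sum(p1[b[[2]]]) - sum(p2[b[[2]]]))))
  den <- sum(sapply(branches, function(b) b[[1]] * (sum(p1[b[[2]]]) + sum(p2[b[[2]]]))))
  D1 <- gunifrac(rbind(s1 = p1, s2 = p2), tr, alpha = 1)
  expect_lt(abs(D1["s1", "s2"] - num / den), 1e-12)
})

test_that("gunifrac is a bounded semimetric invariant to leaf relabeling", {
  d <- small_dataset()
  rel <- relative_abundance(d$counts)[1:20, ]
  D <- gunifrac(rel, d$tree)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  expect_true(all(D >= 0 & D <= 1))
  # consistent relabeling of leaves and columns leaves distances unchanged
  perm <- sample(colnames(rel))
  tr2 <- d$tree
  map <- setNames(perm, colnames(rel))
  tr2$tip.label <- unname(map[tr2$tip.label])
  rel2 <- rel; colnames(rel2) <- unname(map[colnames(rel)])
  expect_equal(gunifrac(rel2, tr2), D, tolerance = 1e-12)
})

test_that("permanova separates clusters and is seed-reproducible", {
  set.seed(9)
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 10), 10))
  rownames(x) <- paste0("s", 1:20)
  lab <- rep(c("a", "b"), each = 10)
  p1 <- permanova(dist(x), lab, n_perm = 199, seed = 3)
  expect_equal(p1$p_perm, 1 / 200)      # maximal separation: minimal p
  expect_gt(p1$r2, 0.9)
  p2 <- permanova(dist(x), lab, n_perm = 199, seed = 3)
  expect_identical(p1$p_perm, p2$p_perm)
  pw <- permanova(dist(x), lab, n_perm = 99, seed = 3, pairwise = TRUE)
  expect_equal(nrow(pw$pairwise), 1)
  expect_error(permanova(dist(x), c("a", rep("b", 19)), n_perm = 99),
               "singleton")
})

test_that("pcoa reproduces Euclidean geometry", {
  # points on a line: axis 1 recovers the line up to sign/offset
  xs <- c(0, 1, 3, 6)
  d <- dist(xs)
  fit <- pcoa(d, k = 1)
  rec <- fit$coords[, 1]
  expect_equal(unname(abs(diff(rec))), diff(xs), tolerance = 1e-9)
  # planar points: recovered pairwise distances equal the input
  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2)
  f2 <- pcoa(dist(pts), k = 2)
  expect_equal(as.vector(dist(f2$coords)), as.vector(dist(pts)),
               tolerance = 1e-9)
  # duplicated sample lands on identical coordinates
  pts2 <- rbind(pts, pts[1, ])
  f3 <- pcoa(dist(pts2), k = 2)
  expect_equal(unname(f3$coords[11, ]), unname(f3$coords[1, ]),
               tolerance = 1e-8)
  expect_error(pcoa(dist(xs), k = 4), "positive eigenvalue")
})

test_that("distance to reference excludes self and tracks the rhythm", {
  d <- small_dataset()
  rel <- relative_abundance(d$counts)
  D <- gunifrac(rel, d$tree)
  res <- distance_to_reference(D, d$meta, ref_time_h = 1)
  # a reference sample's value is the mean over the *other* reference samples
  ref_ids <- d$meta$sample_id[d$meta$time_h == 1]
  s0 <- ref_ids[1]
  expect_equal(res$distances[s0, "dist_to_ref"],
               mean(D[s0, setdiff(ref_ids, s0)]))
  # strong community rhythm: the distance series is itself rhythmic with a
  # trough near the reference time
  f <- res$fits[["control"]]
  expect_lt(f$p_value, 0.01)
  trough <- (f$phase_h + 12) %% 24
  expect_lt(min(abs(trough - 1), 24 - abs(trough - 1)), 4.5)
  expect_error(distance_to_reference(D, d$meta, ref_time_h = 2), "no samples")
})

test_that("procrustes recognizes congruent and mirrored configurations", {
  set.seed(5)
  A <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("s", 1:15), NULL))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  B <- 3 * A %*% R + 2
  rownames(B) <- rownames(A)
  pr <- procrustes_fit(A, B, n_perm = 199, seed = 1)
  expect_lt(pr$m2, 1e-12)
  expect_equal(pr$p_perm, 1 / 200)
  # mirror image: zero residual when reflections allowed, not otherwise
  Bm <- B %*% diag(c(1, -1)); rownames(Bm) <- rownames(A)
  expect_lt(procrustes_fit(A, Bm, n_perm = 49, seed = 1)$m2, 1e-12)
  expect_gt(procrustes_fit(A, Bm, n_perm = 49, seed = 1,
                           allow_reflection = FALSE)$m2, 0.01)
  expect_error(procrustes_fit(A, B[1:10, ]), "differ")
})
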