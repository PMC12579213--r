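# PI matrix assembly, scaling, family reduction, clustering, positive calls.

fake_score <- function(bait, prey, pi, eff = 100) {
  structure(list(bait = bait, prey = prey, efficiency_pct = eff,
                 snr_mean = if (eff > 0) pi / (eff / 100) else 0,
                 pi_raw = pi, n_cells = 50),
            class = "pair_score")
}

test_that("assembly fills exactly the supplied pairs and rejects duplicates", {
  g <- paste0("G", 1:15); e <- paste0("E", 1:19)
  scores <- list()
  for (gi in g) for (ei in e) {
    scores[[length(scores) + 1]] <- fake_score(gi, ei, stats::runif(1))
  }
  m <- assemble_pi_matrix(scores, g, e)
  expect_equal(sum(!is.na(m$raw)), 285)

  empty <- assemble_pi_matrix(list(), g, e)
  expect_true(all(is.na(empty$raw)))

  one <- assemble_pi_matrix(list(fake_score("G2", "E3", 0.5)), g, e)
  expect_equal(which(!is.na(one$raw)), which(row(one$raw) == 2 & col(one$raw) == 3))

  expect_error(assemble_pi_matrix(list(fake_score("G1", "E1", 0.1),
                                       fake_score("G1", "E1", 0.2)), g, e),
               "duplicate")
})

test_that("scaling divides by the scope maximum and is idempotent", {
  m <- assemble_pi_matrix(
    list(fake_score("A", "X", 0.2), fake_score("B", "X", 0.1),
         fake_score("C", "X", 0.05), fake_score("A", "Y", 0),
         fake_score("B", "Y", 0), fake_score("C", "Y", 0)),
    c("A", "B", "C"), c("X", "Y"))
  sc <- scale_pi(m)
  expect_equal(unname(sc$scaled[, "X"]), c(1, 0.5, 0.25))
  expect_equal(unname(sc$scaled[, "Y"]), c(0, 0, 0))  # all-zero column
  again <- scale_pi(structure(list(gtpases = sc$gtpases,
                                   effectors = sc$effectors, raw = sc$scaled,
                                   efficiency = sc$efficiency, scaled = NULL),
                              class = "pi_matrix"))
  expect_equal(again$scaled, sc$scaled)

  gl <- scale_pi(m, "global")
  expect_equal(max(gl$scaled, na.rm = TRUE), 1)
  expect_equal(gl$scaled["A", "X"], 1)
})

test_that("family reduction takes per-family maxima and matches brute force", {
  g <- paste0("G", 1:15); e <- paste0("E", 1:19)
  fam <- stats::setNames(paste0("F", rep(1:5, length.out = 19)), e)
  withr::with_seed(99, {
    for (rep_i in 1:20) {
      scores <- list()
      for (gi in g) for (ei in e) {
        scores[[length(scores) + 1]] <- fake_score(gi, ei, stats::runif(1))
      }
      m <- assemble_pi_matrix(scores, g, e)
      red <- family_reduce(m, fam)
      # brute-force group max oracle
      for (f in unique(unname(fam))) {
        members <- names(fam)[fam == f]
        oracle <- apply(m$raw[, members, drop = FALSE], 1, max)
        expect_equal(unname(red$raw[, f]), unname(oracle))
      }
    }
  })
  # singleton family passes through; missing mapping errors
  single <- family_reduce(m, stats::setNames(e, e))
  expect_equal(single$raw, m$raw, ignore_attr = TRUE)
  expect_error(family_reduce(m, fam[-1]), "mapping")
})

test_that("family reduction commutes with global scaling", {
  g <- paste0("G", 1:6); e <- paste0("E", 1:8)
  fam <- stats::setNames(paste0("F", rep(1:3, length.out = 8)), e)
  scores <- list()
  withr::with_seed(4, {
    for (gi in g) for (ei in e) {
      scores[[length(scores) + 1]] <- fake_score(gi, ei, stats::runif(1))
    }
  })
  m <- assemble_pi_matrix(scores, g, e)
  a <- family_reduce(scale_pi(m, "global"), fam)$scaled
  b <- scale_pi(family_reduce(m, fam), "global")$scaled
  expect_equal(a, b)
})

test_that("clustering recovers a two-block structure", {
  vals <- matrix(0, 6, 6, dimnames = list(paste0("g", 1:6), paste0("e", 1:6)))
  vals[1:3, 1:3] <- 1; vals[4:6, 4:6] <- 1
  scores <- list()
  for (i in 1:6) for (j in 1:6) {
    scores[[length(scores) + 1]] <-
      fake_score(rownames(vals)[i], colnames(vals)[j], vals[i, j])
  }
  m <- assemble_pi_matrix(scores, rownames(vals), colnames(vals))
  cl <- cluster_pi(m, n_boot = 50, seed = 1)
  expect_equal(cl$rows$k, 2)
  expect_equal(length(unique(cl$rows$labels[1:3])), 1)
  expect_equal(length(unique(cl$rows$labels[4:6])), 1)
  expect_false(cl$rows$labels[1] == cl$rows$labels[4])
  expect_true(all(cl$rows$stability >= 0 & cl$rows$stability <= 1))
})

test_that("clustering is invariant to row permutation", {
  withr::with_seed(2, {
    vals <- matrix(stats::runif(30), 5, 6,
                   dimnames = list(paste0("g", 1:5), paste0("e", 1:6)))
  })
  mk <- function(v) {
    scores <- list()
    for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
      scores[[length(scores) + 1]] <-
        fake_score(rownames(v)[i], colnames(v)[j], v[i, j])
    }
    assemble_pi_matrix(scores, rownames(v), colnames(v))
  }
  cl1 <- cluster_pi(mk(vals), n_boot = 30, seed = 5)
  perm <- c(3, 1, 5, 2, 4)
  cl2 <- cluster_pi(mk(vals[perm, ]), n_boot = 30, seed = 5)
  # same partition up to relabeling
  l1 <- cl1$rows$labels[rownames(vals)]
  l2 <- cl2$rows$labels[rownames(vals)]
  expect_equal(length(unique(paste(l1, l2))), length(unique(l1)))
})

test_that("single-row axis yields one trivial cluster", {
  m <- assemble_pi_matrix(list(fake_score("A", "X", 0.5),
                               fake_score("A", "Y", 0.2)),
                          "A", c("X", "Y"))
  cl <- cluster_pi(m, n_boot = 10, seed = 1)
  expect_equal(cl$rows$k, 1)
})

test_that("positive calls respect both floors and are monotone in them", {
  g <- paste0("G", 1:5); e <- paste0("E", 1:5)
  scores <- list()
  withr::with_seed(8, {
    for (gi in g) for (ei in e) {
      scores[[length(scores) + 1]] <-
        fake_score(gi, ei, stats::runif(1), eff = stats::runif(1, 0, 100))
    }
  })
  m <- assemble_pi_matrix(scores, g, e)
  # zero PI everywhere -> all negative
  m0 <- assemble_pi_matrix(lapply(seq_along(scores), function(i) {
    s <- scores[[i]]; s$pi_raw <- 0; s
  }), g, e)
  expect_false(any(call_positives(m0)))
  # strong entry positive under defaults
  strong <- assemble_pi_matrix(list(fake_score("G1", "E1", 0.5, eff = 100)),
                               g, e)
  expect_true(call_positives(strong)["G1", "E1"])
  # exhaustive floor sweep: count non-increasing in both floors
  pis <- seq(0, 1, by = 0.1); effs <- seq(0, 100, by = 10)
  counts <- outer(pis, effs, Vectorize(function(p, ef) {
    sum(call_positives(m, pi_floor = p, eff_floor = ef))
  }))
  expect_true(all(apply(counts, 2, diff) <= 0))
  expect_true(all(apply(counts, 1, diff) <= 0))
})
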