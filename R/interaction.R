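## GTPase x effector interaction matrix: assembly, scaling, gene-family
## reduction, hierarchical clustering with bootstrap stability, and
## positive-interaction calling.

#' Assemble pair scores into a GTPase-by-effector PI matrix
#'
#' Builds the raw protein-interaction-index matrix over the supplied label
#' rosters. Pairs without a score are recorded as missing (`NA`), which is
#' distinct from a measured zero.
#'
#' @param scores List of `pair_score` objects (one per bait-prey pair).
#' @param gtpases,effectors Ordered label vectors defining the matrix axes.
#' @return A `pi_matrix`: list with `gtpases`, `effectors`, `raw`,
#'   `efficiency` (both matrices, `NA` = missing), `scaled` (`NULL` until
#'   [scale_pi()]), and `scope`.
#' @examples
#' pop <- make_population(50, 0.6, seed = 1)
#' s <- pair_score("Rac1", "PAK1", pop$records)
#' m <- assemble_pi_matrix(list(s), c("Rac1", "RhoA"), c("PAK1", "ROCK1"))
#' m$raw
#' @export
assemble_pi_matrix <- function(scores, gtpases, effectors) {
  raw <- matrix(NA_real_, length(gtpases), length(effectors),
                dimnames = list(gtpases, effectors))
  eff <- raw
  for (s in scores) {
    if (!s$bait %in% gtpases || !s$prey %in% effectors) {
      stop("input error: score labels not in the supplied rosters (",
           s$bait, ", ", s$prey, ")")
    }
    if (!is.na(raw[s$bait, s$prey])) {
      stop("input error: duplicate pair (", s$bait, ", ", s$prey, ")")
    }
    raw[s$bait, s$prey] <- s$pi_raw
    eff[s$bait, s$prey] <- s$efficiency_pct
  }
  structure(list(gtpases = gtpases, effectors = effectors, raw = raw,
                 efficiency = eff, scaled = NULL, scope = NULL),
            class = "pi_matrix")
}

#' @export
print.pi_matrix <- function(x, ...) {
  cat(sprintf("<pi_matrix> %d GTPases x %d effectors, %d/%d cells filled%s\n",
              nrow(x$raw), ncol(x$raw), sum(!is.na(x$raw)), length(x$raw),
              if (!is.null(x$scaled)) paste0(", scaled (", x$scope, ")") else ""))
  invisible(x)
}

#' Scale a PI matrix to [0, 1]
#'
#' Divides each entry by the maximum of its normalization scope: the
#' entry's effector column (default, matching per-effector comparison
#' across GTPases) or the whole matrix. All-zero scopes map to zeros.
#' Idempotent.
#'
#' @param m A `pi_matrix`.
#' @param scope `"per_effector_column"` or `"global"`.
#' @return The `pi_matrix` with `scaled` filled and `scope` set.
#' @export
scale_pi <- function(m, scope = c("per_effector_column", "global")) {
  scope <- match.arg(scope)
  raw <- m$raw
  scaled <- if (scope == "global") {
    mx <- max(raw, na.rm = TRUE)
    if (!is.finite(mx) || mx == 0) raw * 0 else raw / mx
  } else {
    apply(raw, 2, function(col) {
      mx <- suppressWarnings(max(col, na.rm = TRUE))
      if (!is.finite(mx) || mx == 0) col * 0 else col / mx
    })
  }
  dimnames(scaled) <- dimnames(raw)
  m$scaled <- scaled
  m$scope <- scope
  m
}

#' Reduce effectors to gene families by maximum PI
#'
#' Collapses effector columns belonging to one gene family (e.g. PAK1-7 to
#' PAK) by taking, per GTPase, the maximum value over family members.
#' Missing entries are ignored; a family that is missing for all members
#' stays missing.
#'
#' @param m A `pi_matrix` (raw, and scaled if present, are both reduced).
#' @param families Named character vector or two-column data.frame mapping
#'   each effector to its family label.
#' @return A `pi_matrix` over families.
#' @examples
#' fam <- c(PAK1 = "PAK", PAK2 = "PAK", ROCK1 = "ROCK")
#' @export
family_reduce <- function(m, families) {
  if (is.data.frame(families)) {
    families <- stats::setNames(as.character(families[[2]]),
                                as.character(families[[1]]))
  }
  missing_map <- setdiff(m$effectors, names(families))
  if (length(missing_map) > 0) {
    stop("mapping error: effectors without a family: ",
         paste(missing_map, collapse = ", "))
  }
  fam <- families[m$effectors]
  fams <- unique(unname(fam))
  reduce <- function(mat) {
    if (is.null(mat)) return(NULL)
    out <- sapply(fams, function(f) {
      sub <- mat[, fam == f, drop = FALSE]
      apply(sub, 1, function(v) {
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      })
    })
    out <- matrix(out, nrow = nrow(mat),
                  dimnames = list(rownames(mat), fams))
    out
  }
  structure(list(gtpases = m$gtpases, effectors = fams,
                 raw = reduce(m$raw), efficiency = reduce(m$efficiency),
                 scaled = reduce(m$scaled), scope = m$scope),
            class = "pi_matrix")
}

# Stability of a flat partition at k under bootstrap resampling of the
# feature axis: per cluster, the fraction of resamples in which the exact
# member set reappears as a cluster.
boot_stability <- function(values, k, n_boot) {
  base <- stats::cutree(stats::hclust(stats::dist(values), "complete"), k)
  clusters <- split(rownames(values), base)
  hits <- stats::setNames(numeric(length(clusters)), names(clusters))
  for (b in seq_len(n_boot)) {
    cols <- sample(ncol(values), replace = TRUE)
    bv <- values[, cols, drop = FALSE]
    bp <- stats::cutree(stats::hclust(stats::dist(bv), "complete"), k)
    bsets <- split(rownames(values), bp)
    for (ci in seq_along(clusters)) {
      if (any(vapply(bsets, function(s) setequal(s, clusters[[ci]]),
                     logical(1)))) {
        hits[ci] <- hits[ci] + 1
      }
    }
  }
  list(labels = base, stability = hits / n_boot,
       mean_stability = mean(hits / n_boot))
}

cluster_axis <- function(values, n_boot, max_k) {
  n <- nrow(values)
  if (n < 2) {
    return(list(tree = NULL,
                labels = stats::setNames(rep(1L, n), rownames(values)),
                k = 1L, stability = numeric(0)))
  }
  tree <- stats::hclust(stats::dist(values), "complete")
  ks <- seq(2, min(max_k, n - 1))
  if (length(ks) == 0) {
    return(list(tree = tree,
                labels = stats::setNames(rep(1L, n), rownames(values)),
                k = 1L, stability = numeric(0)))
  }
  cand <- lapply(ks, function(k) boot_stability(values, k, n_boot))
  best <- which.max(vapply(cand, `[[`, numeric(1), "mean_stability"))
  list(tree = tree, labels = cand[[best]]$labels, k = ks[best],
       stability = cand[[best]]$stability)
}

#' Hierarchically cluster a PI matrix
#'
#' Complete-linkage clustering on Euclidean distances for GTPases (rows)
#' and effectors (columns) separately. The number of flat clusters on each
#' axis is chosen as the partition with the highest bootstrap stability:
#' the opposite axis is resampled with replacement `n_boot` times and a
#' cluster's stability is the fraction of resamples reproducing it exactly.
#' Missing entries are imputed as 0 for clustering only (screen-negative
#' and missing are displayed identically) and flagged in the result.
#'
#' @param m A `pi_matrix`; clustered on `scaled` when present, else `raw`.
#' @param n_boot Number of bootstrap resamples per axis.
#' @param seed Integer seed for the resampling.
#' @param max_k Largest number of flat clusters considered per axis.
#' @return A `cluster_result`: per-axis `tree` (hclust), `labels`, chosen
#'   `k`, per-cluster `stability`, plus `n_imputed`.
#' @export
cluster_pi <- function(m, n_boot = 100, seed = 1, max_k = 6) {
  values <- if (!is.null(m$scaled)) m$scaled else m$raw
  n_imputed <- sum(is.na(values))
  values[is.na(values)] <- 0
  withr::local_seed(seed)
  rows <- cluster_axis(values, n_boot, max_k)
  cols <- cluster_axis(t(values), n_boot, max_k)
  structure(list(rows = rows, cols = cols, n_imputed = n_imputed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> rows: k=%d, cols: k=%d (%d imputed cells)\n",
              x$rows$k, x$cols$k, x$n_imputed))
  invisible(x)
}

#' Call positive interactions from a PI matrix
#'
#' An entry is positive when its raw PI exceeds `pi_floor` and its
#' efficiency is at least `eff_floor` percent. Missing entries are
#' negative. Both floors are configuration, not fixed constants, because
#' the screen's exact criterion depends on assay calibration.
#'
#' @param m A `pi_matrix` with `raw` and `efficiency` filled.
#' @param pi_floor Strict lower bound on raw PI (default 0).
#' @param eff_floor Minimum efficiency in percent (default 10).
#' @return Logical matrix of positive calls.
#' @export
call_positives <- function(m, pi_floor = 0, eff_floor = 10) {
  pos <- !is.na(m$raw) & m$raw > pi_floor &
    !is.na(m$efficiency) & m$efficiency >= eff_floor
  dimnames(pos) <- dimnames(m$raw)
  pos
}
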