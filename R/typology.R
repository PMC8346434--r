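# Two-fold behavioural clustering: a self-organizing tree algorithm (SOTA)
# partitions the standardized curves into clusters; K-means on the cluster
# median features (t20, t50, t80, total consumed) reduces the clusters to
# behavioural groups, which are labelled A-F by a deterministic rule.

#' Extract kinetic features from a consumption curve
#'
#' t20/t50/t80 are the earliest times at which 20/50/80% of the leaf disk
#' has been consumed (fraction_intact crosses 0.8/0.5/0.2), linearly
#' interpolated between samples; a threshold not reached by `tmax` yields
#' that time = `tmax`. `total_consumed` is 1 minus the final
#' fraction-intact.
#'
#' @param curve A standardized, truncated `consumption_curve`.
#' @param tmax Capping horizon in minutes.
#' @return A list `t20`, `t50`, `t80`, `total_consumed`.
#' @export
extract_features <- function(curve, tmax = 2500) {
  stopifnot(inherits(curve, "consumption_curve"))
  f <- curve$fraction_intact; tt <- curve$time
  if (length(f) == 0 || all(is.na(f))) stop("empty curve")
  crossing <- function(q) {
    thr <- 1 - q
    idx <- which(f <= thr)
    if (length(idx) == 0) return(tmax)
    i <- idx[1]
    if (i == 1) return(min(tt[1], tmax))
    t_cross <- tt[i - 1] + (tt[i] - tt[i - 1]) * (f[i - 1] - thr) / (f[i - 1] - f[i])
    min(t_cross, tmax)
  }
  list(t20 = crossing(0.2), t50 = crossing(0.5), t80 = crossing(0.8),
       total_consumed = 1 - f[length(f)])
}

#' Feature table for a set of curves
#'
#' @param curves A list of `consumption_curve`s.
#' @param tmax Capping horizon.
#' @return A data frame with columns `t20`, `t50`, `t80`,
#'   `total_consumed`, one row per curve.
#' @export
features_table <- function(curves, tmax = 2500) {
  rows <- lapply(curves, extract_features, tmax = tmax)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- names(curves)
  out
}

sota_distance <- function(metric) {
  if (metric == "euclidean") function(x, centroid) sqrt(sum((x - centroid)^2))
  else function(x, centroid) {
    # correlation distance 1 - r; degenerate (constant) profiles fall back
    # to euclidean scaled into [0, 2]
    if (stats::sd(x) == 0 || stats::sd(centroid) == 0)
      return(min(2, sqrt(mean((x - centroid)^2))))
    1 - stats::cor(x, centroid)
  }
}

#' Cluster curves with a self-organizing tree algorithm
#'
#' Divisive growth of a binary tree of SOM-like nodes: the root holds the
#' global centroid and starts with two children; in each cycle the leaves
#' are trained online (each presented curve moves its winning leaf centroid
#' by `alpha_w`, the winner's sibling by `alpha_s` and its parent by
#' `alpha_p`) until the relative change of the total resource (mean
#' member-to-centroid distance) falls below `tol`; then the leaf with
#' maximal resource is split into two children seeded at the leaf centroid
#' plus/minus a small jitter. Growth stops at `n_clusters` leaves.
#' Deterministic given `seed`.
#'
#' @param x Numeric matrix, one curve per row, on a common time grid.
#' @param n_clusters Number of leaf clusters to grow (>= 2, <= nrow(x)).
#' @param alpha_w,alpha_p,alpha_s Learning rates for winner, parent,
#'   sibling.
#' @param tol Relative resource-change convergence tolerance per cycle.
#' @param max_epochs Maximum training epochs per cycle.
#' @param metric `"euclidean"` or `"correlation"`.
#' @param seed Integer seed (presentation order and split jitter).
#' @return A `sota_tree`: list with `centroids` (leaf x grid matrix),
#'   `assignment` (leaf index per curve), `resource` (per leaf),
#'   `cycle_resource` (total resource after each growth cycle), `params`.
#' @export
sota_cluster <- function(x, n_clusters = 14, alpha_w = 0.01, alpha_p = 0.005,
                         alpha_s = 0.001, tol = 1e-4, max_epochs = 50,
                         metric = c("euclidean", "correlation"), seed = 1) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_clusters < 2) stop("n_clusters must be at least 2")
  if (n_clusters > n) stop("n_clusters cannot exceed the number of curves")
  dist_fun <- sota_distance(metric)
  jitter_scale <- 1e-3 * stats::sd(as.vector(x))
  if (!is.finite(jitter_scale) || jitter_scale == 0) jitter_scale <- 1e-3

  with_seed(seed, {
    centroid <- list(colMeans(x))          # node centroids
    parent <- c(NA_integer_)
    children <- list(integer(0))
    # Split a leaf: children seeded at the leaf centroid +/- half the
    # offset to the leaf's farthest member (so each side of the member
    # cloud attracts curves), plus a small jitter to break exact ties.
    new_child <- function(p, members) {
      delta <- if (length(members) > 0) {
        dd <- vapply(members, function(i) dist_fun(x[i, ], centroid[[p]]), numeric(1))
        0.5 * (x[members[which.max(dd)], ] - centroid[[p]])
      } else numeric(ncol(x))
      for (s in c(1, -1)) {
        centroid[[length(centroid) + 1]] <<- centroid[[p]] + s * delta +
          jitter_scale * stats::rnorm(ncol(x))
        parent[length(parent) + 1] <<- p
      }
      children[[p]] <<- c(length(centroid) - 1L, length(centroid))
      children[[length(centroid) - 1L]] <<- integer(0)
      children[[length(centroid)]] <<- integer(0)
    }
    new_child(1L, seq_len(n))

    leaves <- function() which(vapply(children, length, integer(1)) == 0)

    assign_all <- function() {
      lv <- leaves()
      cent <- do.call(rbind, centroid[lv])
      d <- vapply(seq_along(lv), function(j)
        apply(x, 1, dist_fun, centroid = cent[j, ]), numeric(n))
      if (!is.matrix(d)) d <- matrix(d, nrow = n)
      win <- max.col(-d, ties.method = "first")
      list(leaf = lv[win], dist = d[cbind(seq_len(n), win)])
    }

    train_epochs <- function() {
      prev <- Inf
      for (epoch in seq_len(max_epochs)) {
        ord <- sample.int(n)
        lv <- leaves()
        for (i in ord) {
          xi <- x[i, ]
          dd <- vapply(lv, function(node) dist_fun(xi, centroid[[node]]), numeric(1))
          wnode <- lv[which.min(dd)]
          centroid[[wnode]] <<- centroid[[wnode]] + alpha_w * (xi - centroid[[wnode]])
          p <- parent[wnode]
          if (!is.na(p)) {
            sib <- setdiff(children[[p]], wnode)
            if (length(sib) == 1 && length(children[[sib]]) == 0)
              centroid[[sib]] <<- centroid[[sib]] + alpha_s * (xi - centroid[[sib]])
            centroid[[p]] <<- centroid[[p]] + alpha_p * (xi - centroid[[p]])
          }
        }
        a <- assign_all()
        res <- mean(a$dist)
        if (is.finite(prev) && abs(prev - res) <= tol * max(prev, .Machine$double.eps))
          return(res)
        prev <- res
      }
      prev
    }

    # Rescue dead leaves: a leaf that attracts no curve is re-seeded on the
    # farthest member of the richest (highest total deviation) leaf with at
    # least 2 members; sitting exactly on a curve, it then owns it. Returns
    # TRUE if anything was re-seeded.
    fix_dead <- function() {
      changed <- FALSE
      repeat {
        a <- assign_all()
        lv <- leaves()
        dead <- lv[!lv %in% a$leaf]
        if (length(dead) == 0 || all(a$dist == 0)) break
        tot_by_leaf <- vapply(lv, function(nd) sum(a$dist[a$leaf == nd]), numeric(1))
        sizes <- vapply(lv, function(nd) sum(a$leaf == nd), numeric(1))
        tot_by_leaf[sizes < 2] <- -Inf
        if (!any(is.finite(tot_by_leaf))) break
        donor <- lv[which.max(tot_by_leaf)]
        members <- which(a$leaf == donor)
        far <- members[which.max(a$dist[members])]
        centroid[[dead[1]]] <<- x[far, ]
        changed <- TRUE
      }
      changed
    }

    # One growth cycle: train to convergence; if leaves died, rescue and
    # retrain, a bounded number of times.
    train_cycle <- function() {
      res <- train_epochs()
      for (attempt in 1:5) {
        if (!fix_dead()) break
        res <- train_epochs()
      }
      res
    }

    cycle_resource <- train_cycle()
    while (length(leaves()) < n_clusters) {
      a <- assign_all()
      lv <- leaves()
      res_by_leaf <- vapply(lv, function(node) {
        m <- a$leaf == node
        if (!any(m)) 0 else mean(a$dist[m])
      }, numeric(1))
      target <- if (all(res_by_leaf == 0)) {
        sizes <- vapply(lv, function(node) sum(a$leaf == node), numeric(1))
        lv[which.max(sizes)]
      } else lv[which.max(res_by_leaf)]
      new_child(target, which(a$leaf == target))
      cycle_resource <- c(cycle_resource, train_cycle())
    }
    fix_dead()   # final pass, no retraining: re-seeded leaves keep their curve

    a <- assign_all()
    lv <- leaves()
    leaf_index <- match(a$leaf, lv)
    resource <- vapply(seq_along(lv), function(j) {
      m <- leaf_index == j
      if (!any(m)) 0 else mean(a$dist[m])
    }, numeric(1))
    structure(list(centroids = do.call(rbind, centroid[lv]),
                   assignment = leaf_index,
                   resource = resource,
                   cycle_resource = cycle_resource,
                   n_clusters = length(lv),
                   params = list(alpha_w = alpha_w, alpha_p = alpha_p,
                                 alpha_s = alpha_s, tol = tol,
                                 max_epochs = max_epochs, metric = metric,
                                 seed = seed)),
              class = "sota_tree")
  })
}

#' @export
print.sota_tree <- function(x, ...) {
  cat(sprintf("SOTA tree: %d leaf clusters over %d curves; total resource %.4g\n",
              x$n_clusters, length(x$assignment), mean(x$resource)))
  invisible(x)
}

#' Median features per SOTA cluster
#'
#' @param tree A `sota_tree`.
#' @param features The per-curve feature table ([features_table()]), rows
#'   aligned with the clustering input.
#' @return A data frame with one row per cluster: `cluster`, `n`, and the
#'   component-wise median `t20`, `t50`, `t80`, `total_consumed`.
#' @export
summarize_clusters <- function(tree, features) {
  stopifnot(inherits(tree, "sota_tree"))
  if (nrow(features) != length(tree$assignment))
    stop("features rows must match the clustered curves")
  out <- lapply(seq_len(tree$n_clusters), function(k) {
    m <- tree$assignment == k
    if (!any(m)) stop("empty cluster ", k)
    data.frame(cluster = k, n = sum(m),
               t20 = stats::median(features$t20[m]),
               t50 = stats::median(features$t50[m]),
               t80 = stats::median(features$t80[m]),
               total_consumed = stats::median(features$total_consumed[m]))
  })
  do.call(rbind, out)
}

#' Group clusters by K-means on their median features
#'
#' Features are z-scored (columns with zero spread are left at 0) before
#' Hartigan-Wong K-means with `n_restarts` random starts; deterministic
#' given `seed`.
#'
#' @param cluster_features Output of [summarize_clusters()] (or any data
#'   frame with columns `t20`, `t50`, `t80`, `total_consumed`).
#' @param k Number of behavioural groups.
#' @param seed Integer seed.
#' @param n_restarts K-means restarts.
#' @return A list: `group` (assignment per cluster), `centers` (group
#'   centroid features on the original scale), `tot_withinss`.
#' @export
kmeans_group <- function(cluster_features, k = 6, seed = 1, n_restarts = 50) {
  feats <- as.matrix(cluster_features[, c("t20", "t50", "t80", "total_consumed")])
  if (k > nrow(feats)) stop("k cannot exceed the number of clusters")
  if (k == nrow(feats))   # singleton groups, zero within-group SS
    return(list(group = seq_len(k), centers = as.data.frame(feats),
                tot_withinss = 0))
  z <- scale(feats)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z[is.nan(z)] <- 0
  fit <- with_seed(seed,
    stats::kmeans(z, centers = k, nstart = n_restarts, iter.max = 100,
                  algorithm = "Hartigan-Wong"))
  centers <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(feats[fit$cluster == g, , drop = FALSE])))
  list(group = fit$cluster, centers = as.data.frame(centers),
       tot_withinss = fit$tot.withinss)
}

#' Label behavioural groups A-F
#'
#' Deterministic rule encoding the verbal type descriptions, applied to the
#' 6 group centroid features in order: F is the group with the lowest total
#' consumption; among the rest, A has the lowest t50 (immediate, fast
#' feeders); E has the highest t20 (most reluctant starters; t50 breaks
#' ties); C has the largest t80 - t50 spread (fast start, late finish); B
#' has the lower t50 of the remaining two (feeds fast after its wait); D is
#' the leftover intermediate. Ties are broken by group index. Groups tied
#' on all four features are an error (degenerate typology).
#'
#' @param group_features Data frame of 6 group centroids with columns
#'   `t20`, `t50`, `t80`, `total_consumed`.
#' @return A character vector of letters, one per group (row).
#' @export
assign_labels <- function(group_features) {
  gf <- as.data.frame(group_features)[, c("t20", "t50", "t80", "total_consumed")]
  if (nrow(gf) != 6) stop("exactly 6 groups are required, got ", nrow(gf))
  if (anyDuplicated(gf) > 0) stop("degenerate typology: two groups share identical features")
  letters_out <- rep(NA_character_, 6)
  remaining <- seq_len(6)
  take <- function(score) {
    # lowest score wins; ties broken by group index (order is stable)
    g <- remaining[order(score, remaining)[1]]
    remaining <<- setdiff(remaining, g)
    g
  }
  letters_out[take(gf$total_consumed[remaining])] <- "F"
  letters_out[take(gf$t50[remaining])] <- "A"
  letters_out[take(-(gf$t20[remaining] + 1e-9 * gf$t50[remaining]))] <- "E"
  letters_out[take(-(gf$t80[remaining] - gf$t50[remaining]))] <- "C"
  letters_out[take(gf$t50[remaining])] <- "B"
  letters_out[remaining] <- "D"
  letters_out
}

#' Assign each curve its behavioural letter
#'
#' @param typology A `behavior_typology` (see [build_typology()]).
#' @return A character vector of letters, one per clustered curve.
#' @export
classify_curves <- function(typology) {
  stopifnot(inherits(typology, "behavior_typology"))
  typology$letters[typology$group[typology$tree$assignment]]
}

#' Run the full two-fold typology
#'
#' SOTA on the curve matrix, K-means on the cluster median features, and
#' letter assignment.
#'
#' @param curve_mat Curve matrix (rows = curves; see [curve_matrix()]).
#' @param features Per-curve feature table aligned with `curve_mat`.
#' @param n_clusters SOTA leaf count.
#' @param n_groups Number of behavioural groups (6 for A-F labels).
#' @param seed Integer seed for both clustering stages.
#' @param ... Passed to [sota_cluster()].
#' @return A `behavior_typology`: `tree`, `cluster_medians`, `group` (per
#'   cluster), `group_centers`, `letters` (per group), `curve_letters`.
#' @export
build_typology <- function(curve_mat, features, n_clusters = 14, n_groups = 6,
                           seed = 1, ...) {
  tree <- sota_cluster(curve_mat, n_clusters = n_clusters, seed = seed, ...)
  med <- summarize_clusters(tree, features)
  km <- kmeans_group(med, k = n_groups, seed = seed)
  letters_map <- if (n_groups == 6) assign_labels(km$centers)
                 else paste0("G", seq_len(n_groups))
  out <- structure(list(tree = tree, cluster_medians = med, group = km$group,
                        group_centers = km$centers, letters = letters_map),
                   class = "behavior_typology")
  out$curve_letters <- classify_curves(out)
  names(out$curve_letters) <- rownames(curve_mat)
  out
}

#' @export
print.behavior_typology <- function(x, ...) {
  cat(sprintf("behavior_typology: %d clusters -> %d groups (%s)\n",
              x$tree$n_clusters, length(x$letters),
              paste(sort(unique(x$letters)), collapse = "")))
  print(table(type = x$curve_letters))
  invisible(x)
}
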