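#' @title Cluster detection and growth analysis
#' @description
#' Vesicles are grouped into condensate clusters through their synapsin
#' linkers: two synapsin beads (the C domain in the bi-domain model) closer
#' than a cutoff of 4 reduced units (under the minimum-image convention)
#' belong to the same synapsin cluster, and vesicles join a cluster when
#' their synapsins do. Connectivity is resolved by union-find over a
#' spatial-index edge set.
#' @name cluster-analysis
NULL

# Weighted quick-union with path halving.
.union_find <- function(n_nodes, edges) {
  parent <- seq_len(n_nodes)
  size <- rep(1L, n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) {
        if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
        parent[b] <- a
        size[a] <- size[a] + size[b]
      }
    }
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

#' Synapsin proximity edges in a snapshot
#'
#' Edge between two interacting synapsin beads (mono: the bead; bi: the C
#' domain) whenever their minimum-image distance is at most `cutoff`.
#' Found with a periodic cell grid; identical to the all-pairs result.
#'
#' @param snapshot a `vc_state`.
#' @param cutoff clustering distance, reduced units (default 4).
#' @return two-column integer matrix of synapsin indices (into the
#'   snapshot's synapsin subset, see [synapsin_positions] ordering).
#' @export
synapsin_adjacency <- function(snapshot, cutoff = 4) {
  stopifnot(inherits(snapshot, "vc_state"), cutoff > 0)
  sp <- synapsin_positions(snapshot)
  if (nrow(sp$positions) < 2)
    return(matrix(integer(0), 0, 2))
  neighbor_pairs_cpp(sp$positions[, 1], sp$positions[, 2],
                     snapshot$box_length, cutoff)
}

#' Vesicle cluster partition of a snapshot
#'
#' Union-find over the synapsin adjacency, then vesicles are merged
#' through their synapsins' components (a vesicle node is linked to each
#' of its synapsins). Vesicles without synapsins are singletons.
#'
#' @inheritParams synapsin_adjacency
#' @return object of class `vc_cluster_partition`: `assignment` (cluster
#'   label per vesicle, 1..n_clusters), `sizes` (vesicles per cluster),
#'   `n_vesicles`.
#' @export
vesicle_clusters <- function(snapshot, cutoff = 4) {
  stopifnot(inherits(snapshot, "vc_state"))
  nv <- max(snapshot$vesicle_id)
  sp <- synapsin_positions(snapshot)
  ns <- nrow(sp$positions)
  edges <- synapsin_adjacency(snapshot, cutoff)
  # nodes: 1..nv vesicles, nv+1..nv+ns synapsins
  own <- cbind(sp$vesicle_id, nv + seq_len(ns))
  all_edges <- rbind(edges + nv, own)
  comp <- .union_find(nv + ns, all_edges)
  labels <- match(comp[seq_len(nv)], unique(comp[seq_len(nv)]))
  structure(list(assignment = labels,
                 sizes = as.integer(table(labels)),
                 n_vesicles = nv),
            class = "vc_cluster_partition")
}

#' @export
print.vc_cluster_partition <- function(x, ...) {
  cat(sprintf("<vc_cluster_partition> %d vesicles in %d clusters (mean %.2f, max %d)\n",
              x$n_vesicles, length(x$sizes), mean_cluster_size(x),
              max(x$sizes)))
  invisible(x)
}

#' Mean cluster size
#'
#' Arithmetic mean of vesicles per cluster, singletons included
#' (`by = "cluster"`, the default), or the vesicle-weighted mean
#' (`by = "vesicle"`: the expected cluster size of a randomly picked
#' vesicle).
#'
#' @param partition a `vc_cluster_partition`.
#' @param by averaging convention.
#' @return mean cluster size (>= 1).
#' @export
mean_cluster_size <- function(partition, by = c("cluster", "vesicle")) {
  by <- match.arg(by)
  s <- partition$sizes
  if (!length(s)) stop("empty partition")
  if (by == "cluster") mean(s) else sum(s^2) / sum(s)
}

#' Cluster growth curve of a trajectory
#'
#' Mean and maximum vesicle cluster size per snapshot.
#'
#' @param trajectory a `vc_trajectory`.
#' @param cutoff synapsin clustering cutoff.
#' @param by averaging convention, see [mean_cluster_size()].
#' @return object of class `vc_growth_curve`: data.frame-like list with
#'   `times`, `mean_size`, `max_size`, `n_clusters`.
#' @export
growth_curve <- function(trajectory, cutoff = 4, by = "cluster") {
  stopifnot(inherits(trajectory, "vc_trajectory"))
  ns <- n_snapshots(trajectory)
  mean_size <- max_size <- ncl <- numeric(ns)
  for (i in seq_len(ns)) {
    part <- vesicle_clusters(get_snapshot(trajectory, i), cutoff)
    mean_size[i] <- mean_cluster_size(part, by)
    max_size[i] <- max(part$sizes)
    ncl[i] <- length(part$sizes)
  }
  structure(list(times = trajectory$times, mean_size = mean_size,
                 max_size = max_size, n_clusters = ncl),
            class = "vc_growth_curve")
}

#' @export
print.vc_growth_curve <- function(x, ...) {
  cat(sprintf("<vc_growth_curve> %d snapshots; final mean size %.2f (max %d)\n",
              length(x$times), x$mean_size[length(x$mean_size)],
              x$max_size[length(x$max_size)]))
  invisible(x)
}

#' Classify a growth curve as none / saturated / growing
#'
#' Looks at the trailing `tail_fraction` of the curve: if the tail mean
#' cluster size stays below 1.5, no clusters formed (`"none"`); otherwise
#' the least-squares slope of mean size over the tail, normalized by the
#' tail mean and multiplied by the tail duration (i.e. the fractional
#' growth across the window), decides `"saturated"` (below `slope_tol`)
#' versus `"growing"`.
#'
#' @param curve a `vc_growth_curve` (>= 10 snapshots).
#' @param tail_fraction trailing fraction of snapshots examined.
#' @param slope_tol fractional-growth threshold.
#' @return one of `"none"`, `"saturated"`, `"growing"`.
#' @export
classify_growth <- function(curve, tail_fraction = 0.3, slope_tol = 0.05) {
  stopifnot(inherits(curve, "vc_growth_curve"))
  n <- length(curve$times)
  if (n < 10) stop("need at least 10 snapshots to classify growth")
  tail_idx <- seq.int(max(1L, n - ceiling(tail_fraction * n) + 1L), n)
  t <- curve$times[tail_idx]
  s <- curve$mean_size[tail_idx]
  if (mean(s) < 1.5) return("none")
  slope <- stats::coef(stats::lm.fit(cbind(1, t), s))[2]
  rel_growth <- slope * (max(t) - min(t)) / mean(s)
  if (is.na(rel_growth) || abs(rel_growth) < slope_tol) "saturated"
  else "growing"
}

#' Sweep the (eps, lambda) phase diagram
#'
#' Runs the simulator over a grid of attraction strengths and linker
#' densities (averaging over seeds), recording the final mean cluster size
#' (mean over the trailing `tail_fraction` of snapshots) and the growth
#' class per cell. Failed cells are recorded with `NA` size and class
#' `"error"` rather than aborting the sweep.
#'
#' @param eps_values,lambda_values grid values.
#' @param base_config template [sim_config()]; `eps`, `lambda` and `seed`
#'   are overridden per cell.
#' @param n_seeds replicate seeds per cell (seeds `base_config$seed + 0:(n_seeds-1)`).
#' @param cutoff clustering cutoff.
#' @param tail_fraction trailing window for the final size and the
#'   classifier.
#' @param slope_tol classifier threshold, see [classify_growth()].
#' @param verbose print per-cell progress.
#' @return data.frame with columns `eps`, `lambda`, `seed`,
#'   `final_mean_size`, `growth_class`.
#' @export
phase_diagram <- function(eps_values, lambda_values, base_config,
                          n_seeds = 3, cutoff = 4, tail_fraction = 0.3,
                          slope_tol = 0.05, verbose = FALSE) {
  stopifnot(length(eps_values) >= 1, length(lambda_values) >= 1,
            inherits(base_config, "vc_config"))
  rows <- list()
  for (eps in eps_values) for (lambda in lambda_values)
    for (k in seq_len(n_seeds)) {
      cfg <- base_config
      cfg$eps <- eps
      cfg$lambda <- lambda
      cfg$seed <- base_config$seed + (k - 1L)
      cfg <- validate_config(cfg)
      res <- tryCatch({
        traj <- run_simulation(cfg)
        curve <- growth_curve(traj, cutoff)
        n <- length(curve$times)
        tail_idx <- seq.int(max(1L, n - ceiling(tail_fraction * n) + 1L), n)
        list(size = mean(curve$mean_size[tail_idx]),
             class = classify_growth(curve, tail_fraction, slope_tol))
      }, error = function(e) list(size = NA_real_, class = "error"))
      if (verbose)
        message(sprintf("phase cell eps=%g lambda=%g seed=%d: %s (%.2f)",
                        eps, lambda, cfg$seed, res$class, res$size))
      rows[[length(rows) + 1L]] <-
        data.frame(eps = eps, lambda = lambda, seed = cfg$seed,
                   final_mean_size = res$size, growth_class = res$class)
    }
  do.call(rbind, rows)
}
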