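# Independent oracles used across the suite. These deliberately avoid the
# package's C++ paths: forces via the R kernel functions and an all-pairs
# loop, connectivity via an adjacency matrix and igraph components.

# All-pairs minimum-image force/energy evaluation from the rule table.
brute_forces <- function(state, config) {
  n <- nrow(state$positions)
  L <- state$box_length
  f <- matrix(0, n, 2)
  pe <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    same_v <- state$vesicle_id[i] == state$vesicle_id[j]
    same_d <- !is.na(state$dimer_id[i]) && !is.na(state$dimer_id[j]) &&
      state$dimer_id[i] == state$dimer_id[j]
    kind <- interaction_rule(state$model, state$species[i],
                             state$species[j], same_v, same_d,
                             config$cc_same_vesicle_attract)
    if (kind == "none") next
    d <- state$positions[i, ] - state$positions[j, ]
    d <- d - L * round(d / L)
    r <- sqrt(sum(d^2))
    ps <- pair_sigma(state$radius[i], state$radius[j])
    if (kind == "wca_repulsive") {
      p <- pair_params(config$eps, ps$sigma, ps$r_c)
      Fr <- wca_force(r, p)
      pe <- pe + wca_energy(r, p)
    } else if (kind == "cos_sq_attractive") {
      p <- pair_params(config$eps, ps$sigma, ps$r_c)
      Fr <- cosine_square_force(r, p)
      pe <- pe + cosine_square_energy(r, p)
    } else { # harmonic tether
      bp <- bond_params(config$bond_K, ps$sigma)
      Fr <- harmonic_bond_force(r, bp)
      pe <- pe + harmonic_bond_energy(r, bp)
    }
    fv <- Fr * d / r
    f[i, ] <- f[i, ] + fv
    f[j, ] <- f[j, ] - fv
  }
  list(forces = f, potential_energy = pe)
}

# All-pairs connected-components clustering of vesicles through synapsins.
brute_clusters <- function(state, cutoff = 4) {
  L <- state$box_length
  sel <- which(state$species %in% c("synapsin", "syn_C"))
  nv <- max(state$vesicle_id)
  ns <- length(sel)
  adj <- matrix(FALSE, nv + ns, nv + ns)
  if (ns > 1) {
    pos <- state$positions[sel, , drop = FALSE]
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    dx <- dx - L * round(dx / L)
    dy <- dy - L * round(dy / L)
    close <- sqrt(dx^2 + dy^2) <= cutoff
    adj[nv + seq_len(ns), nv + seq_len(ns)] <- close
  }
  for (k in seq_len(ns)) {
    v <- state$vesicle_id[sel[k]]
    adj[v, nv + k] <- adj[nv + k, v] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership[seq_len(nv)]
  sort(as.integer(table(comp)))
}

# A random small state for oracle-equivalence checks: vesicles dropped
# uniformly (overlaps allowed; the oracle does not care), then relaxed a
# few steps so beads leave their symmetric start.
random_small_state <- function(model, n_ves = 5, box = 80, lambda = 0.4,
                               eps = 3, seed = 1, relax_steps = 200) {
  cfg <- sim_config(model = model, box_length = box, n_vesicles = n_ves,
                    lambda = lambda, eps = eps, n_steps = relax_steps,
                    snapshot_interval = relax_steps, seed = seed)
  st <- initialize_configuration(cfg)
  if (relax_steps > 0) st <- langevin_step(st, cfg, relax_steps)
  list(state = st, config = cfg)
}

# Arithmetic mean of a normal truncated below at `a`.
truncnorm_mean <- function(mean, sd, a) {
  alpha <- (a - mean) / sd
  mean + sd * dnorm(alpha) / (1 - pnorm(alpha))
}
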