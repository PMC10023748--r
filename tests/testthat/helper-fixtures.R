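# Shared fixtures and independent oracles.
#
# The chain fixture is a linear pathway uptake -> m1 -> ... -> biomass with
# one enzyme per internal reaction; its maximal growth has the closed form
#   g(delta) = min(U, min_i 3600 (kcat_i + delta_i) E_i)
# which serves as the analytic FBA oracle. The parallel fixture has two
# one-reaction branches between m1 and m2, so capacities add:
#   g(delta) = min(U, c_1 + c_2).

# Build a chain network: n enzymes e1..en, kcats/mw named vectors.
chain_network <- function(kcats, mw = NULL) {
  n <- length(kcats)
  enz <- names(kcats)
  if (is.null(mw)) mw <- stats::setNames(rep(50, n), enz)
  mets <- paste0("m", seq_len(n + 1))
  rid <- c("upt", paste0("r", seq_len(n)), "biomass")
  S <- matrix(0, n + 1, n + 2, dimnames = list(mets, rid))
  S["m1", "upt"] <- 1
  for (i in seq_len(n)) S[c(i, i + 1), paste0("r", i)] <- c(-1, 1)
  S[n + 1, "biomass"] <- -1
  net <- metabolic_network(S, lb = rep(0, n + 2), ub = rep(1000, n + 2),
                           biomass = "biomass",
                           gpr = c("", enz, ""))
  pairs <- tibble::tibble(enzyme = enz, reaction = paste0("r", seq_len(n)),
                          kcat = unname(kcats), mw = unname(mw[enz]),
                          measured_in_all = TRUE)
  list(network = net, enzymes = enzyme_table(pairs))
}

# Two parallel branches (e1 on b1, e2 on b2) between m1 and m2.
parallel_network <- function(kcats, mw = NULL) {
  stopifnot(length(kcats) == 2)
  enz <- names(kcats)
  if (is.null(mw)) mw <- stats::setNames(rep(50, 2), enz)
  S <- matrix(0, 2, 4, dimnames = list(c("m1", "m2"),
                                       c("upt", "b1", "b2", "biomass")))
  S["m1", "upt"] <- 1
  S[, "b1"] <- c(-1, 1); S[, "b2"] <- c(-1, 1)
  S["m2", "biomass"] <- -1
  net <- metabolic_network(S, lb = rep(0, 4), ub = rep(1000, 4),
                           biomass = "biomass",
                           gpr = c("", enz[1], enz[2], ""))
  pairs <- tibble::tibble(enzyme = enz, reaction = c("b1", "b2"),
                          kcat = unname(kcats), mw = unname(mw[enz]),
                          measured_in_all = TRUE)
  list(network = net, enzymes = enzyme_table(pairs))
}

# Condition rows from explicit abundances (named per enzyme), uptake bound
# U and measured growth mu; pool parameters generous unless given.
manual_condition <- function(id, abundance, mu, U = 1000, ptot = 10,
                             f = 0.5, sigma = 0.5, gam = 50) {
  tibble::tibble(id = id, growth = mu, ptot = ptot, f = f, sigma = sigma,
                 gam = gam, abundance = list(abundance),
                 uptake = list(stats::setNames(U, "upt")),
                 medium = list("upt"))
}

# Analytic maximal growth of the chain fixture.
chain_growth <- function(kcats, E, U, delta = 0) {
  delta <- rep_len(delta, length(kcats))
  min(U, min(3600 * (kcats + delta) * E[names(kcats)]))
}

# Analytic maximal growth of the parallel fixture.
parallel_growth <- function(kcats, E, U, delta = c(0, 0)) {
  min(U, sum(3600 * (kcats + delta) * E[names(kcats)]))
}

# Dense grid-search oracle for the correction objective on instances whose
# growth has a closed form. `growth_fun(delta_matrix)` returns a matrix
# (grid points x conditions) of maximal growth values.
grid_search_objective <- function(deltas, growth_fun, mu, lambda, theta) {
  g <- growth_fun(deltas)                  # points x conditions
  omega <- sweep(-g, 2, mu, "+")
  omega[omega < 0] <- 0
  omega <- omega / rep(mu, each = nrow(g))
  feas <- rowSums(omega > theta) == 0
  obj <- rowMeans(omega) + lambda / ncol(deltas) * rowSums(deltas)
  obj[!feas] <- Inf
  list(objective = min(obj), argmin = deltas[which.min(obj), ])
}
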