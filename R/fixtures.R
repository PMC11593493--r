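#' Parameters for the minimal-cell toy model
#'
#' A four-species feast--famine toy: one balanced metabolite (`intermediate`)
#' and three imbalanced species (`storage`, `enzymes`, `biomass`). Substrate
#' uptake and biomass synthesis are catalysed by `enzymes`; substrate is only
#' available during the feed window. Only `biomass` contributes to the
#' biomass weight vector; `storage` and `enzymes` carry weights used for
#' per-species mass reporting.
#'
#' The kcats, weights and stoichiometric coefficients are fixture parameters
#' chosen so the feast--famine storage behaviour emerges; they are not
#' measured quantities.
#'
#' @param kcat_uptake Turnover of the uptake reaction (h^-1, default 2).
#' @param kcat_biomass Turnover of biomass synthesis (h^-1, default 1).
#' @param feed_end Time the substrate feed stops (h, default 2).
#' @param t_end Cycle length (h, default 4).
#' @param n_steps Grid intervals (default 8).
#' @param feed_ub Absolute substrate availability during the feed window
#'   (mmol g_DW0^-1 h^-1, default 10).
#' @param storage_weight,enzyme_weight,biomass_weight Molecular weights
#'   (g/mmol, default 1 each).
#' @return Named list of parameters.
#' @export
minimal_cell_params <- function(kcat_uptake = 2, kcat_biomass = 1,
                                feed_end = 2, t_end = 4, n_steps = 8,
                                feed_ub = 10, storage_weight = 1,
                                enzyme_weight = 1, biomass_weight = 1) {
  p <- list(kcat_uptake = kcat_uptake, kcat_biomass = kcat_biomass,
            feed_end = feed_end, t_end = t_end, n_steps = as.integer(n_steps),
            feed_ub = feed_ub, storage_weight = storage_weight,
            enzyme_weight = enzyme_weight, biomass_weight = biomass_weight)
  if (any(vapply(p, function(x) !is.numeric(x) || x <= 0, NA)))
    stop("all minimal-cell parameters must be positive", call. = FALSE)
  if (p$feed_end >= p$t_end) stop("need feed_end < t_end", call. = FALSE)
  p
}

#' Build the minimal-cell toy model
#'
#' Reactions: `uptake` (substrate -> intermediate, catalysed), `store`
#' (intermediate -> storage), `mobilize` (storage -> intermediate),
#' `enzyme_synth` (intermediate -> enzymes), `biomass_synth`
#' (intermediate -> biomass, catalysed). The uptake reaction's default
#' bounds are `(0, 0)`; an environment segment opens it to
#' `(0, feed_ub)` on `[0, feed_end)`.
#'
#' @param params A [minimal_cell_params()] list.
#' @return `list(model = cfba_model, grid = cfba_time_grid)`.
#' @export
minimal_cell_model <- function(params = minimal_cell_params()) {
  sp <- rbind(
    species("intermediate", role = "balanced"),
    species("storage", weight = params$storage_weight,
            contributes_to_weight = FALSE, is_storage = TRUE),
    species("enzymes", weight = params$enzyme_weight,
            contributes_to_weight = FALSE),
    species("biomass", weight = params$biomass_weight,
            contributes_to_weight = TRUE))
  rx <- list(
    reaction("uptake", c(intermediate = 1), lb = 0, ub = 0),
    reaction("store", c(intermediate = -1, storage = 1)),
    reaction("mobilize", c(storage = -1, intermediate = 1)),
    reaction("enzyme_synth", c(intermediate = -1, enzymes = 1)),
    reaction("biomass_synth", c(intermediate = -1, biomass = 1)))
  cap <- rbind(
    capacity_rule("uptake", "enzymes", params$kcat_uptake),
    capacity_rule("biomass_synth", "enzymes", params$kcat_biomass))
  env <- environment_profile("uptake", 0, params$feed_end, 0, params$feed_ub)
  model <- cfba_model(sp, rx, capacity = cap, environment = env)
  assert_valid(model)
  list(model = model,
       grid = time_grid(0, params$t_end, params$n_steps))
}

#' Analytic single-species self-replicator
#'
#' One imbalanced species `E` (weight 1) produced from nothing by a single
#' reaction catalysed by `E` itself. Under the explicit-Euler discretization
#' the maximal multiplication factor has the closed form
#' `mu* = (1 + kcat * dt)^N`, which makes this the analytic oracle for the
#' LP engine.
#'
#' @param kcat Turnover number (> 0).
#' @param n_steps Grid intervals.
#' @param t_end Cycle length (h), from 0.
#' @return `list(model, grid)`.
#' @export
self_replicator <- function(kcat = 1, n_steps = 1, t_end = 1) {
  stopifnot(kcat > 0)
  model <- cfba_model(
    species("E", weight = 1, contributes_to_weight = TRUE),
    list(reaction("make_E", c(E = 1))),
    capacity = capacity_rule("make_E", "E", kcat))
  assert_valid(model)
  list(model = model, grid = time_grid(0, t_end, n_steps))
}

#' Closed-form optimum of the self-replicator
#'
#' Independent of the LP engine: iterates the per-interval growth bound
#' `E_{k+1} = E_k * (1 + kcat * dt_k)`.
#'
#' @param kcat Turnover number.
#' @param grid A [time_grid()].
#' @return The maximal multiplication factor.
#' @export
self_replicator_mu <- function(kcat, grid) {
  prod(1 + kcat * grid$dt)
}

#' Random valid cFBA model
#'
#' Deterministic for a fixed seed. The construction guarantees validity and
#' zero-flux feasibility at mu = 1: all reaction bounds contain 0, and a
#' catalysed exchange chain connects an uptake reaction through every
#' balanced metabolite to a weight-contributing imbalanced species, so the
#' model can also grow (mu* > 1) while staying bounded (all upper bounds
#' finite).
#'
#' @param seed Integer seed.
#' @param n_balanced,n_imbalanced Number of balanced / imbalanced species
#'   (each >= 1).
#' @param n_reactions Total number of reactions (>= n_balanced + 1).
#' @param with_quotas If `TRUE`, adds one `min` and one `max` quota on
#'   weight-contributing species (values drawn in \[0, 0.3\] and
#'   \[0.7, 1\]).
#' @return A validated [cfba_model()].
#' @export
random_model <- function(seed, n_balanced = 1, n_imbalanced = 2,
                         n_reactions = 4, with_quotas = FALSE) {
  stopifnot(n_balanced >= 1, n_imbalanced >= 1,
            n_reactions >= n_balanced + 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  bal <- paste0("m", seq_len(n_balanced))
  imb <- paste0("x", seq_len(n_imbalanced))
  sp <- do.call(rbind, c(
    lapply(bal, function(id) species(id, role = "balanced")),
    lapply(seq_along(imb), function(i)
      species(imb[i], weight = round(stats::runif(1, 0.01, 1), 6),
              contributes_to_weight = TRUE,
              is_storage = i == n_imbalanced && n_imbalanced > 1))))

  rx <- list(); cap <- list()
  # backbone: exchange -> m1 -> m2 -> ... -> x1 (weight-contributing)
  rx[[1]] <- reaction("uptake", c(stats::setNames(1, bal[1])),
                      lb = 0, ub = round(stats::runif(1, 1, 10), 4))
  chain <- c(bal, imb[1])
  for (j in seq_len(length(chain) - 1L)) {
    st <- stats::setNames(c(-1, 1), chain[j + 0:1])
    rx[[j + 1L]] <- reaction(paste0("conv", j), st, lb = 0,
                             ub = round(stats::runif(1, 1, 10), 4))
  }
  cap[[1]] <- capacity_rule("uptake", imb[1],
                            round(stats::runif(1, 0.1, 10), 4))
  # extra random reactions among all species, bounds containing zero
  n_extra <- n_reactions - length(rx)
  all_ids <- c(bal, imb)
  for (e in seq_len(max(n_extra, 0L))) {
    k <- sample(2:min(3, length(all_ids)), 1)
    ids <- sample(all_ids, k)
    coef <- stats::setNames(round(stats::runif(k, 0.5, 2), 3) *
                              c(-1, rep(1, k - 1L)), ids)
    rev <- stats::runif(1) < 0.4
    ub <- round(stats::runif(1, 1, 10), 4)
    rid <- paste0("rxn", e)
    rx[[length(rx) + 1L]] <- reaction(rid, coef, reversible = rev,
                                      lb = if (rev) -ub else 0, ub = ub)
    if (stats::runif(1) < 0.5)
      cap[[length(cap) + 1L]] <-
        capacity_rule(rid, sample(imb, 1), round(stats::runif(1, 0.1, 10), 4))
  }
  quo <- NULL
  if (with_quotas) {
    heavy <- imb[1]
    quo <- rbind(quota(heavy, "min", round(stats::runif(1, 0, 0.3), 3)),
                 quota(heavy, "max", round(stats::runif(1, 0.7, 1), 3)))
  }
  model <- cfba_model(sp, rx, capacity = do.call(rbind, cap), quotas = quo)
  assert_valid(model)
  model
}
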