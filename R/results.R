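#' Biomass weight series along a trajectory
#'
#' Total biomass is the weighted sum of the weight-contributing imbalanced
#' amounts at each grid node. `per_species_weight` decomposes the total over
#' contributing species (columns sum to `total_weight` exactly, summed in
#' species order); `per_species_mass` additionally reports
#' `weight_i * M[i,k]` for every imbalanced species with a declared weight,
#' including those excluded from the biomass vector (e.g. storage polymers
#' under lean-biomass accounting).
#'
#' @param traj A [maximize_mu()] trajectory.
#' @param model The model the trajectory was solved from (defaults to the
#'   split model stored in the trajectory).
#' @return Object of class `cfba_biomass_series` with `times`,
#'   `total_weight`, `per_species_weight`, `per_species_mass`.
#' @export
biomass_series <- function(traj, model = traj$model) {
  w <- weight_vector(model)
  w <- w[w > 0]
  amounts <- traj$amounts[names(w), , drop = FALSE]
  psw <- amounts * w
  sp <- model$species[model$species$role == "imbalanced", , drop = FALSE]
  wm <- ifelse(is.na(sp$weight), 0, sp$weight)
  psm <- traj$amounts[sp$id, , drop = FALSE] * wm
  structure(list(times = traj$grid$nodes,
                 total_weight = colSums(psw),
                 per_species_weight = psw,
                 per_species_mass = psm),
            class = "cfba_biomass_series")
}

#' Enzyme-capacity utilization report
#'
#' For every catalysed reaction and interval, the ratio
#' `v[r,k] / (kcat * M[catalyst, k])` (start-of-interval anchoring; `0/0`
#' is defined as 0: no catalyst, no flux). `saturation_node` is the first
#' interval where the ratio reaches `1 - epsilon`, or `NA` if none does.
#'
#' @param traj A trajectory.
#' @param model The (split) model.
#' @param epsilon Relative saturation threshold (default 1e-6).
#' @param denom_floor Capacities below this value (mmol g_DW0^-1 h^-1) are
#'   treated as numerically zero when forming ratios: the solver resolves
#'   constraints only to its feasibility tolerance, so the quotient of two
#'   vanishing numbers would otherwise be pure noise. Default 1e-6.
#' @return Object of class `cfba_capacity_report` with `ratios` (catalysed
#'   reactions x intervals) and `saturation_node` (named integer vector of
#'   0-based interval indices), or a marker list with `empty = TRUE` when
#'   the model has no capacity rules.
#' @export
capacity_report <- function(traj, model = traj$model, epsilon = 1e-6,
                            denom_floor = 1e-6) {
  cap <- model$capacity
  if (!nrow(cap))
    return(structure(list(empty = TRUE, ratios = NULL,
                          saturation_node = NULL),
                     class = "cfba_capacity_report"))
  N <- traj$grid$n_steps
  ratios <- matrix(NA_real_, nrow(cap), N,
                   dimnames = list(cap$reaction_id, paste0("k", 0:(N - 1L))))
  for (q in seq_len(nrow(cap))) {
    v <- traj$fluxes[cap$reaction_id[q], ]
    limit <- cap$kcat[q] * traj$amounts[cap$catalyst_id[q], seq_len(N)]
    ratios[q, ] <- v / pmax(limit, denom_floor)   # 0/0 is 0 by the floor
  }
  sat <- apply(ratios, 1, function(rr) {
    hit <- which(rr >= 1 - epsilon)
    if (length(hit)) hit[1] - 1L else NA_integer_
  })
  structure(list(empty = FALSE, ratios = ratios,
                 saturation_node = sat, epsilon = epsilon),
            class = "cfba_capacity_report")
}

#' Export a solved run as CSV tables plus a manifest
#'
#' Writes `amounts.csv` (nodes x imbalanced species), `fluxes.csv`
#' (intervals x reactions, times at interval starts), `biomass.csv`,
#' `capacity.csv` (empty but for the header when the model has no capacity
#' rules) and `manifest.yaml` (mu*, grid, tolerances, solver, timestamp)
#' into `directory`, overwriting existing files. Times are the first
#' column; numbers are written with full precision.
#'
#' @param traj A trajectory.
#' @param series A [biomass_series()] (computed if `NULL`).
#' @param report A [capacity_report()] (computed if `NULL`).
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(traj, series = NULL, report = NULL, directory) {
  if (is.null(series)) series <- biomass_series(traj)
  if (is.null(report)) report <- capacity_report(traj)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) sprintf("%.17g", col) else col)
    df
  }
  paths <- character(0)
  wr <- function(df, file) {
    p <- file.path(directory, file)
    utils::write.csv(fmt(df), p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  nodes <- traj$grid$nodes
  wr(data.frame(time = nodes, t(traj$amounts), check.names = FALSE),
     "amounts.csv")
  wr(data.frame(time = nodes[-length(nodes)], t(traj$fluxes),
                check.names = FALSE), "fluxes.csv")
  wr(data.frame(time = nodes, total_weight = series$total_weight,
                t(series$per_species_mass), check.names = FALSE),
     "biomass.csv")
  cap_df <- if (report$empty) {
    data.frame(time = numeric(0))
  } else {
    data.frame(time = nodes[-length(nodes)], t(report$ratios),
               check.names = FALSE)
  }
  wr(cap_df, "capacity.csv")
  manifest <- list(
    mu_star = traj$mu_star,
    grid = list(t0 = traj$grid$t0, t_end = traj$grid$tend,
                n_steps = traj$grid$n_steps),
    solver = traj$provenance$solver,
    mu_tol = traj$provenance$mu_tol,
    feas_tol = traj$provenance$feas_tol,
    iterations = traj$provenance$iterations,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mp <- file.path(directory, "manifest.yaml")
  yaml::write_yaml(manifest, mp, precision = 17)
  invisible(c(paths, mp))
}

#' Storage feast--famine predicates
#'
#' Ordinal checks on the per-species mass of `is_storage` species: whether
#' storage mass rises during the feed window and falls after it. Used for
#' qualitative reproduction of feast--famine storage dynamics where no
#' numeric trajectory values are published.
#'
#' @param traj A trajectory.
#' @param model The model.
#' @param feed_end End of the feed window (h).
#' @return `list(accumulates_during_feed, depletes_after_feed)` (logicals;
#'   `NA` when the model has no storage species).
#' @export
storage_dynamics <- function(traj, model = traj$model, feed_end) {
  sp <- model$species
  sto <- sp$id[sp$role == "imbalanced" & sp$is_storage %in% TRUE]
  if (!length(sto))
    return(list(accumulates_during_feed = NA, depletes_after_feed = NA))
  wm <- stats::setNames(ifelse(is.na(sp$weight), 0, sp$weight), sp$id)
  mass <- colSums(traj$amounts[sto, , drop = FALSE] * wm[sto])
  nodes <- traj$grid$nodes
  feed <- nodes <= feed_end + 1e-12
  peak_feed <- max(mass[feed])
  list(accumulates_during_feed = peak_feed > mass[1] + 1e-9,
       depletes_after_feed = mass[length(mass)] < peak_feed - 1e-9)
}
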