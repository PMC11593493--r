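#' Define a species of a cFBA model
#'
#' Species are either *balanced* (assumed at quasi-steady state: net production
#' is zero at every instant) or *imbalanced* (amounts are explicit time-resolved
#' variables: enzymes, storage polymers, biomass components, substrates).
#'
#' @param id Species identifier (unique within a model).
#' @param role Either `"balanced"` or `"imbalanced"`.
#' @param name Free-text name; defaults to `id`.
#' @param weight Mass per amount (g/mmol). Required for imbalanced species
#'   (0 is permitted for bookkeeping species that carry no mass); must be
#'   absent (`NA`) for balanced species.
#' @param contributes_to_weight Logical; whether the species enters the
#'   biomass weight vector `w` used for the initial normalization
#'   `w' M(t0) = initial_weight` and for quota denominators. Must be `FALSE`
#'   for balanced species and for species with `weight = 0`.
#' @param is_storage Logical flag marking storage polymers (glycogen,
#'   polyphosphate, PHA, ...). Informational by default; see
#'   [cfba_model()]'s `exempt_storage_from_cycle`.
#' @return A one-row `data.frame` to be passed to [cfba_model()].
#' @seealso [reaction()], [cfba_model()]
#' @export
species <- function(id, role = c("imbalanced", "balanced"), name = id,
                    weight = NA_real_, contributes_to_weight = NA,
                    is_storage = FALSE) {
  role <- match.arg(role)
  if (is.na(contributes_to_weight)) {
    contributes_to_weight <- role == "imbalanced" && !is.na(weight) && weight > 0
  }
  data.frame(id = as.character(id), name = as.character(name), role = role,
             weight = as.numeric(weight),
             contributes_to_weight = as.logical(contributes_to_weight),
             is_storage = as.logical(is_storage),
             stringsAsFactors = FALSE)
}

#' Define a reaction of a cFBA model
#'
#' @param id Reaction identifier.
#' @param stoichiometry Named numeric vector mapping species ids to signed
#'   coefficients (negative = consumed, positive = produced), in mmol per
#'   unit flux.
#' @param reversible Logical. Irreversible reactions must have `lb >= 0`.
#' @param lb,ub Default flux bounds (mmol g_DW0^-1 h^-1), used at times not
#'   covered by an environment profile segment.
#' @return A list of class `cfba_reaction`.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     lb = if (reversible) -Inf else 0, ub = Inf) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  structure(list(id = as.character(id),
                 stoichiometry = stoichiometry,
                 reversible = isTRUE(reversible),
                 lb = as.numeric(lb), ub = as.numeric(ub)),
            class = "cfba_reaction")
}

#' Define an enzyme-capacity rule
#'
#' Caps a reaction's flux by its catalyst amount:
#' `v_r(t) <= kcat * M_e(t)` where `M_e` is an imbalanced species. The bound
#' is an upper limit, not an exact value. One rule per reaction.
#'
#' @param reaction_id Catalysed reaction.
#' @param catalyst_id Imbalanced species acting as the catalyst.
#' @param kcat Turnover number (flux units per mmol catalyst, i.e. h^-1).
#' @return One-row `data.frame`.
#' @export
capacity_rule <- function(reaction_id, catalyst_id, kcat) {
  data.frame(reaction_id = as.character(reaction_id),
             catalyst_id = as.character(catalyst_id),
             kcat = as.numeric(kcat), stringsAsFactors = FALSE)
}

#' Define a composition quota
#'
#' Constrains a species' share of total biomass weight at given grid nodes:
#' `w_i M_i(t_k) {=, >=, <=} value * sum_j w_j M_j(t_k)`.
#'
#' @param species_id Imbalanced, weight-contributing species.
#' @param kind `"exact"`, `"min"` or `"max"`.
#' @param value Dimensionless fraction in \[0, 1\].
#' @param time_points Integer vector of 0-based grid node indices (`0` is
#'   `t0`, `N` is `t_end`), or the token `"ALL"` (every node).
#' @return One-row `data.frame` (`time_points` packed as a comma string).
#' @export
quota <- function(species_id, kind = c("exact", "min", "max"), value,
                  time_points = "ALL") {
  kind <- match.arg(kind)
  tp <- if (identical(time_points, "ALL")) "ALL" else
    paste(as.integer(time_points), collapse = ",")
  data.frame(species_id = as.character(species_id), kind = kind,
             value = as.numeric(value), time_points = tp,
             stringsAsFactors = FALSE)
}

#' Define a piecewise-constant environment profile for one reaction
#'
#' Each segment `[t_start, t_end)` (half-open) replaces the reaction's default
#' bounds while it covers the queried time; outside all segments the default
#' bounds apply. Used to encode feast--famine substrate feeds, light cycles,
#' oxygen availability, etc.
#'
#' @param reaction_id Reaction the profile applies to.
#' @param t_start,t_end Numeric vectors of segment limits (h).
#' @param lb,ub Numeric vectors of bounds per segment.
#' @return `data.frame` with one row per segment.
#' @export
environment_profile <- function(reaction_id, t_start, t_end, lb, ub) {
  data.frame(reaction_id = as.character(reaction_id),
             t_start = as.numeric(t_start), t_end = as.numeric(t_end),
             lb = as.numeric(lb), ub = as.numeric(ub),
             stringsAsFactors = FALSE)
}

#' Assemble a cFBA model
#'
#' @param species `data.frame` from stacked [species()] rows.
#' @param reactions List of [reaction()] objects.
#' @param capacity `data.frame` from stacked [capacity_rule()] rows (or `NULL`).
#' @param quotas `data.frame` from stacked [quota()] rows (or `NULL`).
#' @param environment `data.frame` from stacked [environment_profile()] rows
#'   (or `NULL`).
#' @param initial_weight Total initial biomass the simulation is normalized
#'   to (g_DW, default 1).
#' @param exempt_storage_from_cycle If `TRUE`, species flagged `is_storage`
#'   are exempted from the cyclic equality `M(t_end) = mu * M(t0)` (their end
#'   amounts are free, subject to non-negativity). Default `FALSE`: storage
#'   obeys strict cyclicity.
#' @return Object of class `cfba_model`.
#' @export
cfba_model <- function(species, reactions, capacity = NULL, quotas = NULL,
                       environment = NULL, initial_weight = 1,
                       exempt_storage_from_cycle = FALSE) {
  empty_cap <- data.frame(reaction_id = character(), catalyst_id = character(),
                          kcat = numeric(), stringsAsFactors = FALSE)
  empty_quo <- data.frame(species_id = character(), kind = character(),
                          value = numeric(), time_points = character(),
                          stringsAsFactors = FALSE)
  empty_env <- data.frame(reaction_id = character(), t_start = numeric(),
                          t_end = numeric(), lb = numeric(), ub = numeric(),
                          stringsAsFactors = FALSE)
  if (inherits(reactions, "cfba_reaction")) reactions <- list(reactions)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  structure(list(
    species = species,
    reactions = reactions,
    capacity = if (is.null(capacity) || !nrow(capacity)) empty_cap else capacity,
    quotas = if (is.null(quotas) || !nrow(quotas)) empty_quo else quotas,
    environment = if (is.null(environment) || !nrow(environment)) empty_env else environment,
    initial_weight = as.numeric(initial_weight),
    exempt_storage_from_cycle = isTRUE(exempt_storage_from_cycle)
  ), class = "cfba_model")
}

#' @export
print.cfba_model <- function(x, ...) {
  sp <- x$species
  cat("cFBA model:", nrow(sp), "species (",
      sum(sp$role == "balanced"), "balanced /",
      sum(sp$role == "imbalanced"), "imbalanced ),",
      length(x$reactions), "reactions,",
      nrow(x$capacity), "capacity rules,",
      nrow(x$quotas), "quotas,",
      nrow(x$environment), "environment segments\n")
  cat("initial weight:", x$initial_weight, "g_DW;",
      "storage exempt from cycle:", x$exempt_storage_from_cycle, "\n")
  invisible(x)
}

imbalanced_ids <- function(model) {
  model$species$id[model$species$role == "imbalanced"]
}

balanced_ids <- function(model) {
  model$species$id[model$species$role == "balanced"]
}

#' Biomass weight vector
#'
#' One entry per imbalanced species: the molecular weight for species with
#' `contributes_to_weight = TRUE`, zero otherwise. This is the `w` of the
#' initial normalization `w' M(t0) = initial_weight`.
#'
#' @param model A validated [cfba_model()].
#' @return Named numeric vector over imbalanced species.
#' @export
weight_vector <- function(model) {
  sp <- model$species[model$species$role == "imbalanced", , drop = FALSE]
  w <- ifelse(sp$contributes_to_weight, sp$weight, 0)
  stats::setNames(as.numeric(w), sp$id)
}

#' Stoichiometric matrix
#'
#' @param model A [cfba_model()].
#' @return Sparse `Matrix` (species x reactions), rows ordered as
#'   `model$species$id`, columns as `names(model$reactions)`.
#' @export
stoich_matrix <- function(model) {
  sp_ids <- model$species$id
  rx_ids <- names(model$reactions)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (cj in seq_along(model$reactions)) {
    st <- model$reactions[[cj]]$stoichiometry
    ri <- match(names(st), sp_ids)
    i <- c(i, ri); j <- c(j, rep.int(cj, length(st))); x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(sp_ids), length(rx_ids)),
                       dimnames = list(sp_ids, rx_ids))
}

diag_entry <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a cFBA model
#'
#' Checks every structural invariant: id uniqueness and resolution, role/
#' weight consistency, reversibility vs bounds, capacity catalysts being
#' imbalanced, quota species contributing to weight and values in \[0, 1\],
#' environment segments non-overlapping with `lb <= ub`, and the presence of
#' at least one weight-contributing imbalanced species.
#'
#' @param model A [cfba_model()].
#' @return A `data.frame` of diagnostics (columns `severity`, `location`,
#'   `message`); zero rows means the model is valid. Nothing is raised;
#'   callers may escalate with [assert_valid()].
#' @export
validate_model <- function(model) {
  d <- list()
  add <- function(sev, loc, msg) d[[length(d) + 1L]] <<- diag_entry(sev, loc, msg)
  sp <- model$species
  if (anyDuplicated(sp$id))
    add("error", "species", paste("duplicate species ids:",
        paste(unique(sp$id[duplicated(sp$id)]), collapse = ", ")))
  rx_ids <- names(model$reactions)
  if (anyDuplicated(rx_ids))
    add("error", "reactions", paste("duplicate reaction ids:",
        paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", ")))
  for (k in seq_len(nrow(sp))) {
    s <- sp[k, ]
    loc <- paste0("species:", s$id)
    if (s$role == "balanced") {
      if (!is.na(s$weight))
        add("error", loc, "balanced species must not carry a weight")
      if (isTRUE(s$contributes_to_weight))
        add("error", loc, "balanced species cannot contribute to weight")
    } else {
      if (is.na(s$weight))
        add("error", loc, "imbalanced species requires a weight (g/mmol)")
      else if (s$weight < 0)
        add("error", loc, "weight must be >= 0")
      else if (s$weight == 0 && isTRUE(s$contributes_to_weight))
        add("error", loc, "zero-weight species cannot contribute to weight")
    }
  }
  imb <- sp$id[sp$role == "imbalanced" & sp$contributes_to_weight %in% TRUE]
  if (!length(imb))
    add("error", "model", "no imbalanced species contributes to weight")
  for (r in model$reactions) {
    loc <- paste0("reaction:", r$id)
    if (!length(r$stoichiometry))
      add("error", loc, "empty stoichiometry")
    unknown <- setdiff(names(r$stoichiometry), sp$id)
    if (length(unknown))
      add("error", loc, paste("unknown species in stoichiometry:",
                              paste(unknown, collapse = ", ")))
    if (!r$reversible && r$lb < 0)
      add("error", loc, "irreversible reaction must have lb >= 0")
    if (r$lb > r$ub)
      add("error", loc, "lb exceeds ub")
  }
  cap <- model$capacity
  if (nrow(cap)) {
    if (anyDuplicated(cap$reaction_id))
      add("error", "capacity", "more than one capacity rule for a reaction")
    for (k in seq_len(nrow(cap))) {
      loc <- paste0("capacity:", cap$reaction_id[k])
      if (!cap$reaction_id[k] %in% rx_ids)
        add("error", loc, "unknown reaction id")
      ci <- match(cap$catalyst_id[k], sp$id)
      if (is.na(ci))
        add("error", loc, paste("unknown catalyst id:", cap$catalyst_id[k]))
      else if (sp$role[ci] != "imbalanced")
        add("error", loc, paste("catalyst", cap$catalyst_id[k],
                                "must be an imbalanced species"))
      if (!is.na(cap$kcat[k]) && cap$kcat[k] <= 0)
        add("error", loc, "kcat must be > 0")
    }
  }
  quo <- model$quotas
  for (k in seq_len(nrow(quo))) {
    loc <- paste0("quota:", quo$species_id[k])
    si <- match(quo$species_id[k], sp$id)
    if (is.na(si))
      add("error", loc, "unknown species id")
    else if (!isTRUE(sp$contributes_to_weight[si]))
      add("error", loc, "quota species must contribute to weight")
    if (is.na(quo$value[k]) || quo$value[k] < 0 || quo$value[k] > 1)
      add("error", loc, "quota value must lie in [0, 1]")
    if (!quo$kind[k] %in% c("exact", "min", "max"))
      add("error", loc, paste("unknown quota kind:", quo$kind[k]))
  }
  env <- model$environment
  if (nrow(env)) {
    for (rid in unique(env$reaction_id)) {
      loc <- paste0("environment:", rid)
      if (!rid %in% rx_ids) add("error", loc, "unknown reaction id")
      seg <- env[env$reaction_id == rid, , drop = FALSE]
      seg <- seg[order(seg$t_start), , drop = FALSE]
      if (any(seg$lb > seg$ub)) add("error", loc, "segment with lb > ub")
      if (any(seg$t_start >= seg$t_end))
        add("error", loc, "segment with t_start >= t_end")
      if (nrow(seg) > 1 && any(seg$t_end[-nrow(seg)] > seg$t_start[-1] + 1e-12))
        add("error", loc, "overlapping segments")
    }
  }
  if (!length(d)) return(diag_entry(character(0), character(0), character(0))[0, ])
  do.call(rbind, d)
}

#' Stop unless a model validates
#' @param model A [cfba_model()].
#' @return The model, invisibly.
#' @export
assert_valid <- function(model) {
  d <- validate_model(model)
  err <- d[d$severity == "error", , drop = FALSE]
  if (nrow(err))
    stop("invalid cFBA model:\n", paste0("  [", err$location, "] ",
         err$message, collapse = "\n"), call. = FALSE)
  invisible(model)
}

#' Split catalysed reversible reactions into irreversible pairs
#'
#' Enzyme-capacity bounds are one-sided, so both directions of a catalysed
#' reversible reaction must appear as separate non-negative columns of the
#' stoichiometric matrix. Each such reaction `r` with bounds `[lb, ub]` is
#' replaced by `r_fwd` (same stoichiometry, bounds `[0, ub]`, or `[0, Inf]`
#' when `ub` is infinite) and `r_rev` (negated stoichiometry, bounds
#' `[0, |lb|]`); the capacity rule is duplicated onto both with the same kcat,
#' and any environment profile is mapped segment-wise (`[max(0,lb), max(0,ub)]`
#' forward, `[max(0,-ub), max(0,-lb)]` reverse). Uncatalysed reversible
#' reactions are left unchanged. Idempotent.
#'
#' @param model A validated [cfba_model()].
#' @return A new validated `cfba_model`.
#' @export
split_reversible_catalysed <- function(model) {
  assert_valid(model)
  cap_rx <- model$capacity$reaction_id
  targets <- vapply(model$reactions,
                    function(r) r$reversible && r$id %in% cap_rx, NA)
  if (!any(targets)) return(model)
  new_rx <- list(); new_cap <- list(); new_env <- list()
  for (r in model$reactions) {
    if (!(r$reversible && r$id %in% cap_rx)) {
      new_rx[[r$id]] <- r
      next
    }
    fwd <- reaction(paste0(r$id, "_fwd"), r$stoichiometry, reversible = FALSE,
                    lb = 0, ub = max(r$ub, 0))
    rev <- reaction(paste0(r$id, "_rev"), -r$stoichiometry, reversible = FALSE,
                    lb = 0, ub = if (is.finite(r$lb)) abs(min(r$lb, 0)) else Inf)
    new_rx[[fwd$id]] <- fwd
    new_rx[[rev$id]] <- rev
    k <- model$capacity[model$capacity$reaction_id == r$id, , drop = FALSE]
    new_cap[[length(new_cap) + 1L]] <-
      capacity_rule(fwd$id, k$catalyst_id, k$kcat)
    new_cap[[length(new_cap) + 1L]] <-
      capacity_rule(rev$id, k$catalyst_id, k$kcat)
    seg <- model$environment[model$environment$reaction_id == r$id, , drop = FALSE]
    if (nrow(seg)) {
      new_env[[length(new_env) + 1L]] <- environment_profile(
        fwd$id, seg$t_start, seg$t_end, pmax(seg$lb, 0), pmax(seg$ub, 0))
      new_env[[length(new_env) + 1L]] <- environment_profile(
        rev$id, seg$t_start, seg$t_end, pmax(-seg$ub, 0), pmax(-seg$lb, 0))
    }
  }
  untouched_cap <- model$capacity[!(model$capacity$reaction_id %in%
                                    names(which(targets))), , drop = FALSE]
  untouched_env <- model$environment[!(model$environment$reaction_id %in%
                                       names(which(targets))), , drop = FALSE]
  out <- cfba_model(
    species = model$species,
    reactions = new_rx,
    capacity = rbind(untouched_cap, do.call(rbind, new_cap)),
    quotas = model$quotas,
    environment = rbind(untouched_env, do.call(rbind, new_env)),
    initial_weight = model$initial_weight,
    exempt_storage_from_cycle = model$exempt_storage_from_cycle)
  assert_valid(out)
  out
}

#' Effective flux bounds at a time point
#'
#' Returns the bounds of the environment segment covering `t` (segments are
#' half-open `[t_start, t_end)`), or the reaction's default bounds when no
#' segment covers `t`.
#'
#' @param model A [cfba_model()].
#' @param reaction_id Reaction to query.
#' @param t Time (h).
#' @return Numeric `c(lb, ub)`.
#' @export
bounds_at <- function(model, reaction_id, t) {
  r <- model$reactions[[reaction_id]]
  if (is.null(r)) stop("unknown reaction id: ", reaction_id, call. = FALSE)
  seg <- model$environment[model$environment$reaction_id == reaction_id, ,
                           drop = FALSE]
  if (nrow(seg)) {
    hit <- which(seg$t_start <= t & t < seg$t_end)
    if (length(hit)) {
      hit <- hit[1L]
      return(c(seg$lb[hit], seg$ub[hit]))
    }
  }
  c(r$lb, r$ub)
}

#' Time grid for the cycle
#'
#' Discretizes `[t0, t_end]` into `n_steps` intervals. Fluxes are piecewise
#' constant on intervals; amounts live on the `n_steps + 1` nodes. A
#' non-uniform grid may be supplied through `nodes`.
#'
#' @param t0,t_end Cycle limits (h), `t0 < t_end`.
#' @param n_steps Number of intervals `N >= 1`.
#' @param nodes Optional strictly increasing numeric vector of length
#'   `n_steps + 1` overriding the uniform nodes (must start at `t0` and end
#'   at `t_end`).
#' @return Object of class `cfba_time_grid` with elements `t0`, `tend`,
#'   `n_steps`, `nodes`, `dt`.
#' @export
time_grid <- function(t0, t_end, n_steps, nodes = NULL) {
  n_steps <- as.integer(n_steps)
  if (!is.finite(t0) || !is.finite(t_end) || t0 >= t_end)
    stop("need t0 < t_end", call. = FALSE)
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  if (is.null(nodes)) {
    nodes <- seq(t0, t_end, length.out = n_steps + 1L)
  } else {
    if (length(nodes) != n_steps + 1L || any(diff(nodes) <= 0) ||
        abs(nodes[1] - t0) > 1e-12 || abs(nodes[length(nodes)] - t_end) > 1e-12)
      stop("nodes must be strictly increasing from t0 to t_end with length n_steps + 1",
           call. = FALSE)
  }
  structure(list(t0 = t0, tend = t_end, n_steps = n_steps,
                 nodes = as.numeric(nodes), dt = diff(as.numeric(nodes))),
            class = "cfba_time_grid")
}

#' @export
print.cfba_time_grid <- function(x, ...) {
  cat("time grid: [", x$t0, ",", x$tend, "] h,", x$n_steps, "intervals\n")
  invisible(x)
}

# node indices a quota applies to, as 0-based integers
quota_nodes <- function(tp, n_steps) {
  if (identical(tp, "ALL")) return(0:n_steps)
  idx <- as.integer(strsplit(tp, ",", fixed = TRUE)[[1]])
  if (any(is.na(idx)) || any(idx < 0) || any(idx > n_steps))
    stop("quota time_points outside grid node range 0..", n_steps, call. = FALSE)
  idx
}
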