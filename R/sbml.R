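# SBML L3V1 interchange with a dedicated cFBA annotation namespace.
#
# SBML core has no vocabulary for species roles, molecular weights,
# kcat/catalyst links, quotas or time-varying bounds, so those ride in
# namespaced annotation blocks (one per species/reaction plus one
# model-level block). Balanced species are ordinary SBML species with a
# role="balanced" annotation -- the quasi-steady-state constraint is an
# engine concern, not an SBML semantics concern. One compartment ("cell")
# is emitted; compartments are not part of the cFBA math.

CFBA_NS <- "https://cfba-r.invalid/ns/cfba/v1"
SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

num2str <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NaN"
    else if (v == Inf) "INF"
    else if (v == -Inf) "-INF"
    else sprintf("%.17g", v)
  }, "")
}

str2num <- function(s) {
  vapply(s, function(v) {
    if (is.na(v)) return(NA_real_)
    switch(v, INF = Inf, `-INF` = -Inf, `NaN` = NaN, as.numeric(v))
  }, 0, USE.NAMES = FALSE)
}

#' Write a cFBA model as SBML Level 3 Version 1
#'
#' Emits core SBML (compartment, species, reactions with the standard
#' `reversible` attribute and reactant/product stoichiometry) plus cFBA
#' annotations in the namespace `https://cfba-r.invalid/ns/cfba/v1`:
#' per-species `role`, `weight` (g/mmol), `contributesToWeight`,
#' `isStorage`; per-reaction default bounds, a `capacity` element
#' (catalyst, kcat) and an `environment` segment list; model-level
#' `initialWeight`, `exemptStorageFromCycle` and the quota list. Numbers
#' are serialized with 17 significant digits so they round-trip bit-exactly;
#' infinite bounds use the SBML tokens `INF` / `-INF`.
#'
#' @param model A validated [cfba_model()].
#' @param path Output file path (`.xml`).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  assert_valid(model)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            `xmlns:cfba` = CFBA_NS,
                            level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "cfba_model")

  ann <- xml2::xml_add_child(mdl, "annotation")
  mann <- xml2::xml_add_child(ann, "cfba:model",
                              initialWeight = num2str(model$initial_weight),
                              weightUnits = "g_DW",
                              exemptStorageFromCycle =
                                tolower(model$exempt_storage_from_cycle))
  if (nrow(model$quotas)) {
    ql <- xml2::xml_add_child(mann, "cfba:listOfQuotas")
    for (q in seq_len(nrow(model$quotas))) {
      xml2::xml_add_child(ql, "cfba:quota",
                          species = model$quotas$species_id[q],
                          kind = model$quotas$kind[q],
                          value = num2str(model$quotas$value[q]),
                          units = "dimensionless",
                          timePoints = model$quotas$time_points[q])
    }
  }

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", constant = "true")

  spl <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (k in seq_len(nrow(model$species))) {
    s <- model$species[k, ]
    sn <- xml2::xml_add_child(spl, "species", id = s$id, name = s$name,
                              compartment = "cell",
                              hasOnlySubstanceUnits = "true",
                              boundaryCondition = "false", constant = "false")
    sann <- xml2::xml_add_child(sn, "annotation")
    attrs <- list(role = s$role)
    if (!is.na(s$weight)) {
      attrs$weight <- num2str(s$weight)
      attrs$weightUnits <- "g_per_mmol"
    }
    attrs$contributesToWeight <- tolower(isTRUE(s$contributes_to_weight))
    attrs$isStorage <- tolower(isTRUE(s$is_storage))
    do.call(xml2::xml_add_child, c(list(sann, "cfba:species"), attrs))
  }

  rxl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(rxl, "reaction", id = r$id,
                              reversible = tolower(r$reversible),
                              fast = "false")
    st <- r$stoichiometry
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      ln <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in seq_along(reac))
        xml2::xml_add_child(ln, "speciesReference", species = names(reac)[i],
                            stoichiometry = num2str(-reac[i]),
                            constant = "true")
    }
    if (length(prod)) {
      ln <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in seq_along(prod))
        xml2::xml_add_child(ln, "speciesReference", species = names(prod)[i],
                            stoichiometry = num2str(prod[i]),
                            constant = "true")
    }
    rann <- xml2::xml_add_child(rn, "annotation")
    rb <- xml2::xml_add_child(rann, "cfba:reaction",
                              lb = num2str(r$lb), ub = num2str(r$ub),
                              fluxUnits = "mmol_per_gDW0_per_h")
    cap <- model$capacity[model$capacity$reaction_id == r$id, , drop = FALSE]
    if (nrow(cap))
      xml2::xml_add_child(rb, "cfba:capacity", catalyst = cap$catalyst_id,
                          kcat = num2str(cap$kcat), kcatUnits = "per_h")
    env <- model$environment[model$environment$reaction_id == r$id, ,
                             drop = FALSE]
    if (nrow(env)) {
      en <- xml2::xml_add_child(rb, "cfba:environment", timeUnits = "h")
      for (g in seq_len(nrow(env)))
        xml2::xml_add_child(en, "cfba:segment",
                            start = num2str(env$t_start[g]),
                            end = num2str(env$t_end[g]),
                            lb = num2str(env$lb[g]), ub = num2str(env$ub[g]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_ns <- c(s = SBML_NS, c = CFBA_NS)

# file-level problems (missing, malformed, wrong format) vs content-level
# problems (parseable SBML whose cFBA content is invalid); cmd_validate
# maps them to different exit codes
stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("cfba_parse_error", "error")))
}
stop_content <- function(...) {
  stop(errorCondition(paste0(...), class = c("cfba_content_error", "error")))
}

#' Read a cFBA model from SBML
#'
#' Parses a file written in the dialect of [write_sbml()]. Standard SBML
#' structure is checked (root element, level/version, model, species with
#' required attributes); every species must carry a cFBA `role` annotation
#' -- a file without them fails with a parse error naming each offending
#' element. Annotation elements in foreign namespaces are ignored with a
#' warning. The returned model passes [validate_model()].
#'
#' @param path SBML file path.
#' @return A validated [cfba_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop_parse("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_parse("malformed XML in ", path,
                                                 ": ", conditionMessage(e)))
  root <- xml2::xml_name(doc)
  if (root != "sbml" || !identical(xml2::xml_attr(doc, "level"), "3") ||
      !identical(xml2::xml_attr(doc, "version"), "1"))
    stop_parse("not an SBML Level 3 Version 1 document: ", path)
  mdl <- xml2::xml_find_first(doc, "./s:model", sbml_ns)
  if (inherits(mdl, "xml_missing"))
    stop_parse("SBML document has no <model> element")

  foreign <- xml2::xml_find_all(
    doc, ".//s:annotation/*[namespace-uri() != '" %+% CFBA_NS %+% "']",
    sbml_ns)
  if (length(foreign))
    warning("ignoring ", length(foreign),
            " annotation element(s) in foreign namespaces: ",
            paste(unique(xml2::xml_name(foreign)), collapse = ", "),
            call. = FALSE)

  sp_nodes <- xml2::xml_find_all(mdl, "./s:listOfSpecies/s:species", sbml_ns)
  if (!length(sp_nodes)) stop_content("SBML model lists no species")
  missing_role <- character(0)
  sp_rows <- list()
  for (sn in sp_nodes) {
    sid <- xml2::xml_attr(sn, "id")
    ann <- xml2::xml_find_first(sn, "./s:annotation/c:species", sbml_ns)
    role <- if (inherits(ann, "xml_missing")) NA_character_ else
      xml2::xml_attr(ann, "role")
    if (is.na(role)) { missing_role <- c(missing_role, sid); next }
    wt <- xml2::xml_attr(ann, "weight")
    sp_rows[[length(sp_rows) + 1L]] <- species(
      sid, role = role, name = xml2::xml_attr(sn, "name") %||% sid,
      weight = if (is.na(wt)) NA_real_ else str2num(wt),
      contributes_to_weight =
        identical(xml2::xml_attr(ann, "contributesToWeight"), "true"),
      is_storage = identical(xml2::xml_attr(ann, "isStorage"), "true"))
  }
  if (length(missing_role))
    stop_content("species without cFBA role annotation: ",
                 paste(missing_role, collapse = ", "))
  sp <- do.call(rbind, sp_rows)

  rx <- list(); cap <- list(); env <- list()
  for (rn in xml2::xml_find_all(mdl, "./s:listOfReactions/s:reaction",
                                sbml_ns)) {
    rid <- xml2::xml_attr(rn, "id")
    st <- numeric(0)
    for (ref in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference",
                                   sbml_ns))
      st[xml2::xml_attr(ref, "species")] <-
        -str2num(xml2::xml_attr(ref, "stoichiometry"))
    for (ref in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference",
                                   sbml_ns)) {
      sid <- xml2::xml_attr(ref, "species")
      st[sid] <- (if (sid %in% names(st)) st[sid] else 0) +
        str2num(xml2::xml_attr(ref, "stoichiometry"))
    }
    rann <- xml2::xml_find_first(rn, "./s:annotation/c:reaction", sbml_ns)
    if (inherits(rann, "xml_missing"))
      stop_content("reaction '", rid, "' lacks the cFBA reaction annotation")
    rx[[rid]] <- reaction(
      rid, st,
      reversible = identical(xml2::xml_attr(rn, "reversible"), "true"),
      lb = str2num(xml2::xml_attr(rann, "lb")),
      ub = str2num(xml2::xml_attr(rann, "ub")))
    cn <- xml2::xml_find_first(rann, "./c:capacity", sbml_ns)
    if (!inherits(cn, "xml_missing"))
      cap[[length(cap) + 1L]] <- capacity_rule(
        rid, xml2::xml_attr(cn, "catalyst"),
        str2num(xml2::xml_attr(cn, "kcat")))
    for (seg in xml2::xml_find_all(rann, "./c:environment/c:segment", sbml_ns))
      env[[length(env) + 1L]] <- environment_profile(
        rid, str2num(xml2::xml_attr(seg, "start")),
        str2num(xml2::xml_attr(seg, "end")),
        str2num(xml2::xml_attr(seg, "lb")),
        str2num(xml2::xml_attr(seg, "ub")))
  }

  mann <- xml2::xml_find_first(mdl, "./s:annotation/c:model", sbml_ns)
  iw <- 1; exempt <- FALSE; quo <- list()
  if (!inherits(mann, "xml_missing")) {
    iwa <- xml2::xml_attr(mann, "initialWeight")
    if (!is.na(iwa)) iw <- str2num(iwa)
    exempt <- identical(xml2::xml_attr(mann, "exemptStorageFromCycle"), "true")
    for (qn in xml2::xml_find_all(mann, "./c:listOfQuotas/c:quota", sbml_ns)) {
      qsp <- xml2::xml_attr(qn, "species")
      if (!qsp %in% sp$id)
        stop_content("quota annotation references unknown species id '",
                     qsp, "'")
      tp <- xml2::xml_attr(qn, "timePoints")
      quo[[length(quo) + 1L]] <- quota(
        qsp, kind = xml2::xml_attr(qn, "kind"),
        value = str2num(xml2::xml_attr(qn, "value")),
        time_points = if (identical(tp, "ALL")) "ALL" else
          as.integer(strsplit(tp, ",", fixed = TRUE)[[1]]))
    }
  }
  model <- cfba_model(sp, rx, capacity = do.call(rbind, cap),
                      quotas = do.call(rbind, quo),
                      environment = do.call(rbind, env),
                      initial_weight = iw,
                      exempt_storage_from_cycle = exempt)
  tryCatch(assert_valid(model),
           error = function(e) stop_content(conditionMessage(e)))
  model
}

`%+%` <- function(a, b) paste0(a, b)
`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
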