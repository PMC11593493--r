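# Tabular (CSV) model description: one file per entity.
#
#   species.csv     id,name,role,weight,contributes_to_weight,is_storage
#   reactions.csv   id,reversible,lb,ub,stoichiometry
#                   (stoichiometry packed as "species:coef;species:coef")
#   capacity.csv    reaction_id,catalyst_id,kcat
#   quotas.csv      species_id,kind,value,time_points   ("ALL" or "0|3|8")
#   environment.csv reaction_id,t_start,t_end,lb,ub
#
# capacity/quotas/environment files are optional. Infinite bounds are
# written as "Inf"/"-Inf" (base-R numeric parsing).

pack_stoich <- function(st) {
  paste(sprintf("%s:%.17g", names(st), unname(st)), collapse = ";")
}

unpack_stoich <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                  vapply(parts, `[[`, "", 1))
}

#' Write a cFBA model as a directory of CSV tables
#'
#' @param model A validated [cfba_model()].
#' @param directory Target directory (created if needed).
#' @return Invisibly, the directory.
#' @seealso [read_model_csv()] for the file layout.
#' @export
write_model_csv <- function(model, directory) {
  assert_valid(model)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(directory, f),
                                           row.names = FALSE, quote = FALSE)
  wcsv(model$species, "species.csv")
  rdf <- data.frame(
    id = vapply(model$reactions, `[[`, "", "id"),
    reversible = vapply(model$reactions, `[[`, NA, "reversible"),
    lb = vapply(model$reactions, `[[`, 0, "lb"),
    ub = vapply(model$reactions, `[[`, 0, "ub"),
    stoichiometry = vapply(model$reactions,
                           function(r) pack_stoich(r$stoichiometry), ""),
    stringsAsFactors = FALSE)
  wcsv(rdf, "reactions.csv")
  if (nrow(model$capacity)) wcsv(model$capacity, "capacity.csv")
  if (nrow(model$quotas)) {
    q <- model$quotas
    q$time_points <- gsub(",", "|", q$time_points, fixed = TRUE)
    wcsv(q, "quotas.csv")
  }
  if (nrow(model$environment)) wcsv(model$environment, "environment.csv")
  meta <- data.frame(key = c("initial_weight", "exempt_storage_from_cycle"),
                     value = c(sprintf("%.17g", model$initial_weight),
                               tolower(model$exempt_storage_from_cycle)))
  wcsv(meta, "model.csv")
  invisible(directory)
}

#' Read a cFBA model from a directory of CSV tables
#'
#' Expects `species.csv` and `reactions.csv`; `capacity.csv`, `quotas.csv`,
#' `environment.csv` and `model.csv` (initial weight, storage-cycle flag)
#' are optional. See the package source header of this loader for column
#' layouts.
#'
#' @param directory Directory written by [write_model_csv()] (or by hand).
#' @return A validated [cfba_model()].
#' @export
read_model_csv <- function(directory) {
  rcsv <- function(f) {
    p <- file.path(directory, f)
    if (!file.exists(p)) return(NULL)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  num_cols <- function(df, cols) {
    if (is.null(df)) return(df)
    for (cl in intersect(cols, names(df))) df[[cl]] <- as.numeric(df[[cl]])
    df
  }
  sp <- num_cols(rcsv("species.csv"), "weight")
  rdf <- num_cols(rcsv("reactions.csv"), c("lb", "ub"))
  if (is.null(sp) || is.null(rdf))
    stop("directory must contain species.csv and reactions.csv", call. = FALSE)
  sp$role <- as.character(sp$role)
  rx <- lapply(seq_len(nrow(rdf)), function(k)
    reaction(rdf$id[k], unpack_stoich(rdf$stoichiometry[k]),
             reversible = isTRUE(rdf$reversible[k]),
             lb = rdf$lb[k], ub = rdf$ub[k]))
  quo <- num_cols(rcsv("quotas.csv"), "value")
  if (!is.null(quo))
    quo$time_points <- gsub("|", ",", as.character(quo$time_points),
                            fixed = TRUE)
  meta <- rcsv("model.csv")
  iw <- 1; exempt <- FALSE
  if (!is.null(meta)) {
    if ("initial_weight" %in% meta$key)
      iw <- as.numeric(meta$value[meta$key == "initial_weight"])
    if ("exempt_storage_from_cycle" %in% meta$key)
      exempt <- identical(meta$value[meta$key == "exempt_storage_from_cycle"],
                          "true")
  }
  model <- cfba_model(sp, rx,
                      capacity = num_cols(rcsv("capacity.csv"), "kcat"),
                      quotas = quo,
                      environment = num_cols(rcsv("environment.csv"),
                                             c("t_start", "t_end", "lb", "ub")),
                      initial_weight = iw, exempt_storage_from_cycle = exempt)
  assert_valid(model)
  model
}
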