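#' Create a metabolite
#'
#' Metabolites are compartment-tagged chemical species. Species in the
#' `external` compartment are exempt from the steady-state mass balance:
#' they are sources and sinks of the network.
#'
#' @param id Unique, compartment-prefixed identifier (e.g. `"chl_GLU"`).
#' @param name Free-text name; defaults to `id`.
#' @param compartment Compartment label; must belong to the model's
#'   declared compartment set.
#' @param is_external Logical; must be `TRUE` exactly when
#'   `compartment == "external"`.
#' @param n_atoms Optional integer nitrogen atom count, used by
#'   [nitrogen_audit()].
#' @return An object of class `cfba_metabolite`.
#' @export
metabolite <- function(id, name = id, compartment,
                       is_external = identical(compartment, "external"),
                       n_atoms = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is_external != identical(compartment, "external")) {
    stop("metabolite '", id, "': is_external must be TRUE iff compartment == 'external'")
  }
  structure(list(id = id, name = name, compartment = compartment,
                 is_external = is_external, n_atoms = n_atoms),
            class = "cfba_metabolite")
}

#' Create a reaction
#'
#' A reaction is one column of the stoichiometric matrix: a sparse map
#' from metabolite ids to signed coefficients (negative = consumed,
#' positive = produced), flux bounds, and optional annotation.
#'
#' @param id Unique reaction identifier.
#' @param stoich Named numeric vector of nonzero signed coefficients.
#' @param lb,ub Flux lower / upper bounds (flux units). `lb < 0` marks the
#'   reaction reversible.
#' @param subsystem Free-text subsystem label.
#' @param gpr Optional gene association string (`AND`/`OR` tree, e.g.
#'   `"g1 AND (g2 OR g3)"`); empty string means no gene data.
#' @param is_transporter Logical; `TRUE` for inter-compartment transport
#'   (including exchanges with the external space).
#' @return An object of class `cfba_reaction`.
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, subsystem = "",
                     gpr = "", is_transporter = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoich) == 0L || is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "': stoich must be a non-empty named numeric vector")
  }
  if (any(stoich == 0)) {
    stop("reaction '", id, "': zero stoichiometric coefficients are not stored")
  }
  if (anyDuplicated(names(stoich))) {
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  }
  if (lb > ub) stop("reaction '", id, "': lb > ub")
  structure(list(id = id, stoich = stoich, lb = as.numeric(lb),
                 ub = as.numeric(ub), reversible = lb < 0,
                 subsystem = subsystem, gpr = gpr,
                 is_transporter = isTRUE(is_transporter)),
            class = "cfba_reaction")
}

DEFAULT_COMPARTMENTS <- c("cytosol", "chloroplast", "mitochondrion",
                          "peroxisome", "external")

#' Assemble a metabolic model
#'
#' Orders of `metabolites` and `reactions` are preserved (insertion
#' order), so the stoichiometric matrix is reproducible bit-for-bit.
#' All model invariants are checked at construction.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param compartments Declared compartment set.
#' @param id Model identifier.
#' @return An object of class `cfba_model`.
#' @export
metabolic_model <- function(metabolites, reactions,
                            compartments = DEFAULT_COMPARTMENTS,
                            id = "model") {
  stopifnot(is.list(metabolites), is.list(reactions))
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      compartments = compartments),
                 class = "cfba_model")
  validate_model(m)
  m
}

#' @export
print.cfba_model <- function(x, ...) {
  cat("<cfba_model> ", x$id, ": ",
      length(x$metabolites), " metabolites (",
      sum(!met_external(x)), " internal), ",
      length(x$reactions), " reactions, ",
      length(model_genes(x)), " genes\n", sep = "")
  invisible(x)
}

#' Metabolite / reaction identifiers in model order
#' @param model A `cfba_model`.
#' @return Character vector of ids.
#' @export
met_ids <- function(model) vapply(model$metabolites, `[[`, "", "id")

#' @rdname met_ids
#' @export
rxn_ids <- function(model) vapply(model$reactions, `[[`, "", "id")
met_external <- function(model) vapply(model$metabolites, `[[`, NA, "is_external")
rxn_lb <- function(model) vapply(model$reactions, `[[`, 0, "lb")
rxn_ub <- function(model) vapply(model$reactions, `[[`, 0, "ub")
rxn_compartments <- function(model) {
  vapply(model$reactions, function(r) {
    cps <- unique(met_compartment_of(model, names(r$stoich)))
    cps <- setdiff(cps, "external")
    if (length(cps) == 1L) cps else "transport"
  }, "")
}

met_compartment_of <- function(model, ids) {
  comp <- vapply(model$metabolites, `[[`, "", "compartment")
  names(comp) <- met_ids(model)
  unname(comp[ids])
}

#' Gene identifiers referenced by any gene association in the model
#' @param model A `cfba_model`.
#' @return Character vector of gene ids (insertion order of first use).
#' @export
model_genes <- function(model) {
  gprs <- vapply(model$reactions, `[[`, "", "gpr")
  unique(unlist(lapply(gprs[nzchar(gprs)], gpr_genes), use.names = FALSE))
}

#' Validate model invariants
#'
#' Checks id uniqueness, compartment membership, bound sanity,
#' reversibility consistency and that every referenced metabolite is
#' declared. Called by [metabolic_model()]; exported for use after manual
#' edits.
#'
#' @param model A `cfba_model`.
#' @return The model, invisibly; errors name the offending reaction.
#' @export
validate_model <- function(model) {
  mids <- met_ids(model)
  rids <- rxn_ids(model)
  if (anyDuplicated(mids)) stop("duplicate metabolite ids: ",
                                paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids)) stop("duplicate reaction ids: ",
                                paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (met in model$metabolites) {
    if (!met$compartment %in% model$compartments) {
      stop("metabolite '", met$id, "': undeclared compartment '", met$compartment, "'")
    }
    if (met$is_external != identical(met$compartment, "external")) {
      stop("metabolite '", met$id, "': is_external inconsistent with compartment")
    }
  }
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoich), mids)
    if (length(missing)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    if (r$lb > r$ub) stop("reaction '", r$id, "': lb > ub")
    if (r$reversible != (r$lb < 0)) {
      stop("reaction '", r$id, "': reversible flag inconsistent with lb")
    }
  }
  invisible(model)
}

#' Build the stoichiometric matrix
#'
#' Returns the m-by-n matrix S over *internal* metabolites only: entry
#' `S[i, j]` is reaction j's signed coefficient for internal metabolite i.
#' Row order follows the model's metabolite order (externals dropped),
#' column order the reaction order.
#'
#' @param model A `cfba_model`.
#' @return Dense numeric matrix with metabolite / reaction dimnames.
#' @export
build_stoichiometric_matrix <- function(model) {
  validate_model(model)
  internal <- met_ids(model)[!met_external(model)]
  S <- matrix(0, nrow = length(internal), ncol = length(model$reactions),
              dimnames = list(internal, rxn_ids(model)))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    keep <- names(st) %in% internal
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  S
}

#' Report orphan metabolites and dead-end species
#'
#' An internal metabolite that is only ever produced or only ever consumed
#' cannot carry steady-state flux; any reaction touching it is forced to
#' zero. Reversible reactions count as both producers and consumers.
#' Declared metabolites never referenced by a reaction are orphans.
#'
#' @param model A `cfba_model`.
#' @return List with data.frame `dead_ends` (metabolite, mode, reactions)
#'   and character vector `orphans`; both empty for a consistent model.
#' @export
check_structural_consistency <- function(model) {
  validate_model(model)
  internal <- met_ids(model)[!met_external(model)]
  produced <- consumed <- setNames(logical(length(internal)), internal)
  touching <- setNames(vector("list", length(internal)), internal)
  for (r in model$reactions) {
    st <- r$stoich[names(r$stoich) %in% internal]
    for (k in seq_along(st)) {
      mid <- names(st)[k]
      touching[[mid]] <- c(touching[[mid]], r$id)
      if (st[k] > 0 || r$reversible) produced[mid] <- TRUE
      if (st[k] < 0 || r$reversible) consumed[mid] <- TRUE
    }
  }
  referenced <- vapply(touching, function(x) length(x) > 0L, NA)
  orphans <- internal[!referenced]
  bad <- internal[referenced & (!produced | !consumed)]
  dead <- data.frame(metabolite = bad,
                     mode = ifelse(produced[bad], "only-produced", "only-consumed"),
                     reactions = vapply(touching[bad], paste, "", collapse = ";"),
                     stringsAsFactors = FALSE)
  rownames(dead) <- NULL
  list(dead_ends = dead, orphans = orphans)
}

rxn_index <- function(model, ids, context = "reaction") {
  idx <- match(ids, rxn_ids(model))
  if (anyNA(idx)) {
    stop("unknown ", context, " id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Set flux bounds on a reaction
#'
#' Convenience editor returning a modified copy; the reversible flag is
#' re-derived from the new lower bound.
#'
#' @param model A `cfba_model`.
#' @param id Reaction id.
#' @param lb,ub New bounds; omit either to keep it.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  j <- rxn_index(model, id)
  r <- model$reactions[[j]]
  if (!is.null(lb)) r$lb <- as.numeric(lb)
  if (!is.null(ub)) r$ub <- as.numeric(ub)
  if (r$lb > r$ub) stop("reaction '", id, "': lb > ub")
  r$reversible <- r$lb < 0
  model$reactions[[j]] <- r
  model
}
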