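## Plain-text reaction format (".rxn"):
##   tab-separated columns  id  equation  lb  ub  subsystem  gpr
## with the equation grammar
##   coef met (+ coef met)*  ARROW  coef met (+ coef met)*
## where the coefficient is omitted when 1, ARROW is "->" (irreversible)
## or "<>" (reversible) and metabolite ids match [A-Za-z0-9_.-]+.
## Lines starting with "#" are comments. Bounds may be omitted; the
## defaults are [0, 1000] for "->" and [-1000, 1000] for "<>".

COMPARTMENT_PREFIXES <- c(cyt = "cytosol", chl = "chloroplast",
                          mit = "mitochondrion", per = "peroxisome",
                          x = "external")

compartment_from_id <- function(id) {
  pre <- sub("_.*$", "", id)
  unname(COMPARTMENT_PREFIXES[pre])
}

parse_equation <- function(eq, line = NA_integer_) {
  perr <- function(...) stop("parse error (line ", line, "): ", ...)
  arrow <- if (grepl("<>", eq, fixed = TRUE)) "<>"
    else if (grepl("->", eq, fixed = TRUE)) "->"
    else perr("missing or malformed arrow in '", eq, "'")
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) perr("equation must have exactly one arrow: '", eq, "'")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) perr("empty reaction side in '", eq, "'")
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    st <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) perr("empty term in '", eq, "'")
      toks <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) {
        coef <- 1
        met <- toks
      } else if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(coef)) perr("unparseable coefficient '", toks[1], "'")
        met <- toks[2]
      } else {
        perr("malformed term '", tm, "'")
      }
      if (!grepl("^[A-Za-z0-9_.-]+$", met)) perr("invalid metabolite id '", met, "'")
      st[met] <- (if (is.na(match(met, names(st)))) 0 else st[[met]]) + sign * coef
    }
    st
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (k in seq_along(rhs)) {
    met <- names(rhs)[k]
    st[met] <- (if (met %in% names(st)) st[[met]] else 0) + rhs[[k]]
  }
  st <- st[st != 0]
  if (!length(st)) perr("all coefficients cancel in '", eq, "'")
  list(stoich = st, reversible = arrow == "<>")
}

#' Read a metabolic model from the plain-text reaction format
#'
#' Metabolite compartments are inferred from the id prefix
#' (`cyt_`, `chl_`, `mit_`, `per_`, `x_`); an unknown prefix triggers a
#' warning and assignment to the cytosol. Metabolites are declared in
#' order of first appearance.
#'
#' @param path Path to a UTF-8 `.rxn` file.
#' @param id Model id; defaults to the file name.
#' @return A `cfba_model`.
#' @export
read_model <- function(path, id = sub("\\.rxn$", "", basename(path))) {
  lines <- readLines(path, encoding = "UTF-8")
  rxns <- list()
  seen_ids <- character(0)
  met_order <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 2L) {
      stop("parse error (line ", i, "): expected tab-separated id and equation")
    }
    rid <- fields[1]
    if (rid %in% seen_ids) stop("parse error (line ", i, "): duplicate reaction id '", rid, "'")
    eq <- parse_equation(fields[2], line = i)
    ## bounds may arrive as two fields or one space-separated field
    rest <- fields[-(1:2)]
    if (length(rest) >= 1L && grepl("[[:space:]]", rest[1])) {
      rest <- c(strsplit(rest[1], "[[:space:]]+")[[1]], rest[-1])
    }
    num_or <- function(x, default) {
      if (is.na(x) || !nzchar(x)) return(default)
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) stop("parse error (line ", i, "): unparseable bound '", x, "'")
      v
    }
    lb_def <- if (eq$reversible) -1000 else 0
    lb <- num_or(rest[1], lb_def)
    ub <- num_or(rest[2], 1000)
    subsystem <- if (length(rest) >= 3L && !is.na(rest[3])) rest[3] else ""
    gpr <- if (length(rest) >= 4L && !is.na(rest[4])) rest[4] else ""
    if (eq$reversible != (lb < 0)) {
      stop("parse error (line ", i, "): arrow and lower bound disagree for '",
           rid, "' (reversible '<>' requires lb < 0)")
    }
    new_mets <- setdiff(names(eq$stoich), met_order)
    met_order <- c(met_order, new_mets)
    comp <- met_compartments_with_warning(new_mets)
    rxns[[length(rxns) + 1L]] <- list(rid = rid, stoich = eq$stoich, lb = lb,
                                      ub = ub, subsystem = subsystem, gpr = gpr)
    seen_ids <- c(seen_ids, rid)
  }
  comps <- met_compartments_with_warning(met_order, warn = FALSE)
  mets <- lapply(seq_along(met_order), function(k) {
    metabolite(met_order[k], compartment = comps[k])
  })
  reactions <- lapply(rxns, function(r) {
    span <- unique(comps[match(names(r$stoich), met_order)])
    reaction(r$rid, r$stoich, lb = r$lb, ub = r$ub, subsystem = r$subsystem,
             gpr = r$gpr, is_transporter = length(span) > 1L)
  })
  metabolic_model(mets, reactions,
                  compartments = DEFAULT_COMPARTMENTS, id = id)
}

met_compartments_with_warning <- function(ids, warn = TRUE) {
  comp <- compartment_from_id(ids)
  if (warn && anyNA(comp) && length(ids)) {
    warning("unknown compartment prefix for: ",
            paste(ids[is.na(comp)], collapse = ", "),
            "; assigned to cytosol", call. = FALSE)
  }
  comp[is.na(comp)] <- "cytosol"
  comp
}

format_coef <- function(x) {
  s <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  ## strip trailing zeros only after a decimal point
  has_dec <- grepl(".", s, fixed = TRUE)
  s[has_dec] <- sub("\\.?0+$", "", s[has_dec])
  s
}

format_equation <- function(r) {
  st <- r$stoich
  lhs <- st[st < 0]
  rhs <- st[st > 0]
  side <- function(s, flip) {
    paste(vapply(seq_along(s), function(k) {
      coef <- if (flip) -s[[k]] else s[[k]]
      if (coef == 1) names(s)[k] else paste(format_coef(coef), names(s)[k])
    }, ""), collapse = " + ")
  }
  paste(side(lhs, TRUE), if (r$reversible) "<>" else "->", side(rhs, FALSE))
}

#' Write a metabolic model to the plain-text reaction format
#'
#' `read_model(write_model(m, path))` reproduces the stoichiometric
#' matrix, bounds, reversibility and gene associations exactly.
#'
#' @param model A `cfba_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  hdr <- c("# chlorofba reaction file",
           "# id\tequation\tlb\tub\tsubsystem\tgpr")
  rows <- vapply(model$reactions, function(r) {
    paste(r$id, format_equation(r), format_coef(r$lb), format_coef(r$ub),
          r$subsystem, r$gpr, sep = "\t")
  }, "")
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Import an SBML model (Level 2/3)
#'
#' Species become metabolites (`boundaryCondition="true"` marks external
#' species, excluded from the steady-state rows); reactions keep their
#' stoichiometries and reversibility. Without bound annotations, bounds
#' default to [0, 1000] for irreversible and [-1000, 1000] for reversible
#' reactions.
#'
#' @param path Path to an SBML file.
#' @return A `cfba_model`.
#' @export
import_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML import error: ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("SBML import error: no listOfSpecies")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_comp[is.na(sp_comp)] <- "default"
  sp_bnd <- tolower(xml2::xml_attr(sp_nodes, "boundaryCondition")) %in% "true"
  sp_comp[sp_bnd] <- "external"
  mets <- lapply(seq_along(sp_id), function(k) {
    metabolite(sp_id[k], name = xml2::xml_attr(sp_nodes[[k]], "name") %||% sp_id[k],
               compartment = sp_comp[k])
  })
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(nd) {
    rid <- xml2::xml_attr(nd, "id")
    rev <- !identical(tolower(xml2::xml_attr(nd, "reversible")), "false")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(nd, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        sgn <- if (side == "listOfReactants") -1 else 1
        st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0) + sgn * coef
      }
    }
    st <- st[st != 0]
    comp_span <- unique(sp_comp[match(names(st), sp_id)])
    reaction(rid, st, lb = if (rev) -1000 else 0, ub = 1000,
             is_transporter = length(comp_span) > 1L)
  })
  metabolic_model(mets, reactions,
                  compartments = unique(c(sp_comp, "external")),
                  id = sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
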