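#' Generate a layered synthetic network with known essential set
#'
#' Builds a source-to-demand chain of internal metabolites in which some
#' stages carry parallel (redundant) reactions. By construction a
#' reaction is essential for the terminal demand exactly when it is the
#' only reaction of its stage, so the generator records the ground-truth
#' essential set for oracle comparisons. A seeded fraction of stage
#' reactions is reversible.
#'
#' @param n_metabolites Number of internal chain metabolites (>= 1).
#' @param n_reactions Total number of reactions; must equal
#'   `n_metabolites + 1` (importer + chain + exporter) plus the number of
#'   added parallel branches.
#' @param n_parallel_paths Maximum multiplicity of a stage; 1 builds a
#'   pure chain (then `n_reactions` must be exactly `n_metabolites + 1`).
#' @param seed RNG seed; construction is reproducible per seed.
#' @param p_reversible Probability that a stage reaction is reversible.
#' @return A `cfba_model` with attributes `essential_truth` (reaction
#'   ids) and `demand_reaction` (the exporter id).
#' @export
generate_synthetic_network <- function(n_metabolites, n_reactions,
                                       n_parallel_paths = 1, seed = 1,
                                       p_reversible = 0.25) {
  if (n_metabolites < 1 || n_parallel_paths < 1) {
    stop("sizes must be >= 1")
  }
  base_n <- n_metabolites + 1L          # importer + (m-1) steps + exporter
  extra <- n_reactions - base_n
  n_stages <- n_metabolites - 1L
  if (extra < 0) {
    stop("impossible size combination: need at least ", base_n, " reactions")
  }
  if (n_parallel_paths == 1L && extra > 0) {
    stop("impossible size combination: a pure chain (n_parallel_paths = 1) ",
         "has exactly ", base_n, " reactions")
  }
  if (extra > 0 && n_stages == 0L) {
    stop("impossible size combination: no internal stage to parallelise")
  }
  if (extra > n_stages * (n_parallel_paths - 1L)) {
    stop("impossible size combination: at most ", n_parallel_paths - 1L,
         " extra branches per stage")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  mids <- paste0("cyt_M", seq_len(n_metabolites))
  mets <- c(lapply(mids, function(id) metabolite(id, compartment = "cytosol")),
            list(metabolite("x_S", compartment = "external"),
                 metabolite("x_P", compartment = "external")))
  ## branch multiplicities per stage
  mult <- rep(1L, max(n_stages, 0L))
  left <- extra
  while (left > 0L) {
    open <- which(mult < n_parallel_paths)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    mult[pick] <- mult[pick] + 1L
    left <- left - 1L
  }
  rxns <- list(reaction("imp", c(x_S = -1, cyt_M1 = 1),
                        is_transporter = TRUE, subsystem = "exchange"))
  for (s in seq_len(n_stages)) {
    for (k in seq_len(mult[s])) {
      rev <- stats::runif(1) < p_reversible
      rxns[[length(rxns) + 1L]] <- reaction(
        sprintf("stage%d_b%d", s, k),
        setNames(c(-1, 1), c(mids[s], mids[s + 1L])),
        lb = if (rev) -1000 else 0, subsystem = "chain")
    }
  }
  rxns[[length(rxns) + 1L]] <- reaction(
    "exp", setNames(c(-1, 1), c(mids[n_metabolites], "x_P")),
    is_transporter = TRUE, subsystem = "exchange")
  m <- metabolic_model(mets, rxns, id = sprintf("synthetic_s%d", seed))
  truth <- c("imp",
             unlist(lapply(seq_len(n_stages), function(s) {
               if (mult[s] == 1L) sprintf("stage%d_b1", s) else character(0)
             })),
             "exp")
  attr(m, "essential_truth") <- truth
  attr(m, "demand_reaction") <- "exp"
  m
}
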