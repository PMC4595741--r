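## Small hand-built networks used across the suite.

## linear chain: x_A -> A -> B -> x_B (three unit steps)
toy_chain <- function() {
  mets <- list(metabolite("cyt_A", compartment = "cytosol"),
               metabolite("cyt_B", compartment = "cytosol"),
               metabolite("x_A", compartment = "external"),
               metabolite("x_B", compartment = "external"))
  rxns <- list(reaction("imp", c(x_A = -1, cyt_A = 1), is_transporter = TRUE),
               reaction("step", c(cyt_A = -1, cyt_B = 1)),
               reaction("exp", c(cyt_B = -1, x_B = 1), is_transporter = TRUE))
  metabolic_model(mets, rxns, id = "chain")
}

## diamond: two parallel unit paths from A to B
toy_diamond <- function() {
  mets <- list(metabolite("cyt_A", compartment = "cytosol"),
               metabolite("cyt_B", compartment = "cytosol"),
               metabolite("x_A", compartment = "external"),
               metabolite("x_B", compartment = "external"))
  rxns <- list(reaction("imp", c(x_A = -1, cyt_A = 1), is_transporter = TRUE),
               reaction("branch1", c(cyt_A = -1, cyt_B = 1)),
               reaction("branch2", c(cyt_A = -1, cyt_B = 1)),
               reaction("exp", c(cyt_B = -1, x_B = 1), is_transporter = TRUE))
  metabolic_model(mets, rxns, id = "diamond")
}

## two independent routes into one demanded product (for ratio coupling)
toy_two_routes <- function() {
  mets <- list(metabolite("cyt_S", compartment = "cytosol"),
               metabolite("cyt_X", compartment = "cytosol"),
               metabolite("x_S", compartment = "external"),
               metabolite("x_X", compartment = "external"))
  rxns <- list(reaction("imp", c(x_S = -1, cyt_S = 1), is_transporter = TRUE),
               reaction("Vc", c(cyt_S = -1, cyt_X = 1)),
               reaction("Vo", c(cyt_S = -1, cyt_X = 1)),
               reaction("demand", c(cyt_X = -1, x_X = 1), is_transporter = TRUE))
  metabolic_model(mets, rxns, id = "two_routes")
}

## deliberate free-energy cycle: A -> B charges ATP, B -> A is costless
toy_leaky <- function() {
  mets <- list(metabolite("cyt_A", compartment = "cytosol"),
               metabolite("cyt_B", compartment = "cytosol"),
               metabolite("cyt_ATP", compartment = "cytosol"),
               metabolite("cyt_ADP", compartment = "cytosol"),
               metabolite("x_A", compartment = "external"))
  rxns <- list(reaction("imp", c(x_A = -1, cyt_A = 1), is_transporter = TRUE),
               reaction("charge", c(cyt_A = -1, cyt_ADP = -1,
                                    cyt_B = 1, cyt_ATP = 1)),
               reaction("relax", c(cyt_B = -1, cyt_A = 1)),
               reaction("use", c(cyt_ATP = -1, cyt_ADP = 1)))
  metabolic_model(mets, rxns, id = "leaky")
}

## random-but-reproducible synthetic instance set used by the
## property-style oracle comparisons
synthetic_cases <- function(n_cases = 100) {
  lapply(seq_len(n_cases), function(s) {
    nm <- 2 + (s %% 5)               # 2..6 internal metabolites
    base <- nm + 1
    npp <- 2 + (s %% 2)              # 2 or 3 parallel branches
    max_extra <- (nm - 1) * (npp - 1)
    extra <- s %% (max_extra + 1)
    if (extra == 0) npp_eff <- 1 else npp_eff <- npp
    generate_synthetic_network(nm, base + extra,
                               n_parallel_paths = npp_eff, seed = s)
  })
}
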