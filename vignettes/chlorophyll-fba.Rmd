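---
title: "Constraint-based analysis of chlorophyll biosynthesis in a leaf cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of chlorophyll biosynthesis in a leaf cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorofba)
```

## The model and its assumptions

`chlorofba` analyses compartmented plant metabolic networks with flux
balance analysis (FBA). A network is a list of reactions over
compartment-tagged metabolites; at steady state every internal
metabolite is produced exactly as fast as it is consumed,

$$S\,v = 0,\qquad LB \le v \le UB,$$

where $S$ is the stoichiometric matrix over the internal metabolites
(external species are sources and sinks, exempt from the balance) and
$v$ the flux vector. Among all steady states satisfying the imposed
constraints, the engine selects the one minimising the **total absolute
flux**

$$Z = \sum_j |v_j|,$$

the "economy of the enzymic machinery" objective common in plant FBA:
of all ways to meet a fixed demand, the cell is assumed to use the one
requiring the least aggregate enzymatic capacity. The absolute value is
linearised exactly by splitting every reaction into two nonnegative
half-variables ($v = v^+ - v^-$, $Z = \sum (v^+ + v^-)$); at any
optimum the two halves are never simultaneously active, which the test
suite verifies. All reactions, including transporters and the photon
importer, carry weight 1 in the objective — the photon demand is an
outcome of the same minimisation, not a separate stage.

The central application is chlorophyll-a biosynthesis in a rice leaf
cell. The bundled reduced network (`build_leaf_fixture()`,
97 reactions + 7 dissipation/light lumps, 4 compartments) fixes the
chlorophyll exporter at 1.0 flux unit and asks how nitrogen, one-carbon
units, carbon skeletons and reducing power have to move between the
chloroplast, cytosol, mitochondrion and peroxisome to sustain that
export.

## What the demand pins down

Chlorophyll a contains 4 nitrogen atoms, and its exporter is the only
nitrogen sink in the network, so exactly 4.0 units of ammonia must be
imported per unit of pigment regardless of any other choice — split
freely between the cytosolic importer (`NH_3__tx`, feeding GS1) and the
chloroplastic importer (`ex_ammonia_tx`, feeding GS2). Several interior
fluxes are equally pinned by stoichiometry alone, and the package
recovers them from the LP rather than from bookkeeping:

* 8 glutamates enter the tetrapyrrole branch (8 ALA → 4 PBG → 1 ring),
  so the lumped Glu→ALA step carries 8.0;
* the PBG→HMB condensation releases 4 NH~3~ inside the chloroplast;
* the single methyl group consumed per pigment (MgPP→MgPPME, via SAM)
  forces the cytosolic SHMT to run at 1.0, sending 1.0 glycine to the
  mitochondrion, where GDC and SHMT split it 0.5/0.5 — releasing
  0.5 NH~3~ that is exported to the chloroplast;
* GS/GOGAT must therefore cycle at 8.5 (4 imported + 4 + 0.5 released),
  and since GOGAT consumes chloroplastic 2-oxoglutarate supplied only
  by the Mal–2OG antiport, that shuttle also carries 8.5.

These values are invariant across the whole ammonia-importer scan;
`GS2 = 4.5 + a` and `GS1 = 4 − a` as the chloroplastic importer is
fixed at $a = 0 \dots 4$, with the Glu–Gln antiport slaved to GS1.

## Scenarios

Two bundled conditions follow the Rubisco treatment:

* **case 1** — carboxylase only (the oxygenase blocked). Because the
  oxygenase and the C2 cycle waste CO~2~ and NH~3~, an unconstrained
  flux minimisation always abandons the oxygenase; case 1 makes that
  explicit.
* **case 2** — carboxylation:oxygenation coupled at $V_c/V_o = 3$
  (normal air), added as one equality row $v_c - 3v_o = 0$.

Under case 2 the C2 cycle must run: glycolate moves to the peroxisome,
glycine to the mitochondrion, and the mitochondrial GDC ammonia release
rises ~30-fold (15.2 vs 0.5 per unit chlorophyll on the fixture), with
the Mal–2OG shuttle at 23.2. The chloroplast-to-cytosol ammonia
diffusion reaction (`am_diff_tx`) ships bounded to zero; reopening it
is what makes GS2 dispensable (deletion feasible), the model's account
of why GS2 mutants survive only under non-photorespiratory conditions.

## Numerical and design choices

* **Bounds.** Unstated bounds default to [0, 1000] (irreversible) and
  [−1000, 1000] (reversible); 1000 plays the role of "unbounded" and is
  treated as infinite by the LP builder. The photon importer and the
  two light lumps carry explicit 10^6^ bounds because photon flux per
  unit pigment exceeds 1000.
* **Tolerances.** Mass-balance residual ≤ 1e−6 (`balance_tol`), active
  support at |v| > 1e−9 (`support_tol`), FVA classification ties at
  1e−6. These are ordinary double-precision LP practice.
* **Solver.** No assumption is made about an external LP library: the
  package bundles a deterministic two-phase dense simplex (Dantzig
  pricing, lowest-index tie-breaks, Bland fallback against cycling,
  periodic basis refactorisation for numerical hygiene). Solves are
  single-threaded and variable order follows model order, so repeated
  runs are bit-identical. `pracma::linprog` can be selected as an
  alternative backend and the test suite requires the two to agree to
  1e−6 on small problems.
* **FVA.** The objective bound is an inequality
  $\sum|v| \le r \cdot Z^\*$; at $r = 1$ this fixes the optimum, and on
  the leaf fixture every reaction is then pinned (`fva_min = fba_val =
  fva_max`), i.e. the case-1 optimum is unique. Per-reaction solves are
  independent of solve order (tested by shuffling).
* **Essentiality.** A reaction is essential iff forcing its flux to
  zero (both directions) makes the demand infeasible — strict
  infeasibility, not a reduced-optimum threshold, because a linear
  demand is scale-free. Scans default to the active pathway of the
  scenario optimum, with `all_reactions = TRUE` to widen.
* **Light stoichiometry.** The lumped non-cyclic reaction uses
  8 photons : 2 NADPH : 2.9 ATP : 1 O~2~, and the cyclic lump
  2 photons : 1 ATP. The ATP yield of linear flow sits within the
  literature range (≈2.57–3.0 per 2 NADPH depending on the assumed
  H^+^/ATP ratio); the sub-3 value was chosen so that the chloroplast
  runs an ATP surplus under purely carboxylating metabolism but an ATP
  deficit under photorespiration, engaging cyclic photophosphorylation
  in case 2 — the physiologically documented behaviour. This is also
  what makes the importer preference flip: with chloroplastic ATP free
  at the margin (case 1) the GS2 route (importer + GS2, 2 flux units
  per N) beats the GS1 route (importer + GS1 + Glu–Gln antiport,
  3 units); with chloroplastic ATP costing cyclic photon flux (case 2)
  the cytosolic route wins.
* **Malate valve.** Case 2 is infeasible without a route exporting
  chloroplast reducing power to the peroxisome: the cytosolic NADH
  budget cannot cover hydroxypyruvate reduction at photorespiratory
  rates. The fixture therefore includes the chloroplastic NADP-malate
  dehydrogenase (OAA + NADPH → Mal, valve-directional); in case 1 it
  carries zero flux because every use of it is strictly costlier than
  the Mal–OAA antiport route.
* **Nitrogen bookkeeping.** The PBG→HMB step is encoded as
  4 PBG → HMB + 4 NH~3~ for one ring, the accounting on which the
  chloroplastic ammonia budget rests (textbook HMBS deaminates per
  PBG; lumping all four releases into the one condensation step leaves
  every flux unchanged). All metabolites, including cofactors and
  external species, carry true nitrogen atom counts, and
  `nitrogen_audit()` verifies that every reaction balances exactly.
* **Dissipation lumps.** The reduced network omits the biomass economy
  that absorbs respiratory ATP and excess reducing power in a whole
  cell, so maintenance-style lumps (compartmental ATPases, a cytosolic
  NADH oxidase) close the energy balance. They are sinks, not sources:
  the conservation test shows they cannot generate anything. They can
  appear "essential" in deletion scans simply because the forced
  surplus has nowhere else to go.
* **GS2 under diffusion.** With diffusion enabled the flux-minimal
  optimum still uses GS2 (refixing in place is cheaper than diffusing
  and refixing via GS1); GS2's dispensability shows as a feasible
  deletion, which is the claim the scenario tests assert.

## The synthetic generator

`generate_synthetic_network()` builds layered source→demand chains in
which seeded stages carry parallel redundant reactions; a reaction is
essential exactly when it is the only one of its stage, so the
essential set is known by construction. A seeded fraction of stage
reactions is reversible, which makes the relaxed-budget FVA ranges
non-trivial (forward/backward loops within the budget). The generator
emulates the structural features the engine's guarantees depend on —
alternative routes, reversibility, a single demanded product — but not
the things that make real networks hard: cofactor coupling across
compartments, lumped stoichiometries, or biological bounds. Passing the
oracle comparisons on these networks therefore validates the LP
machinery (the optimiser, FVA, deletion logic), not the biological
fidelity of any particular model; that is what the leaf fixture's
pinned-flux checks are for.

Property-style tests run the deletion scan and FVA against brute-force
oracles (orthant enumeration over an independent LP formulation) on 100
seeded networks of at most a dozen reactions, alongside the
mass-balance, nitrogen-closure and conservation invariants. Problem
sizes throughout the suite — a ~110-reaction fixture and ≤12-reaction
synthetic networks — keep every check a desk-scale LP.

## Known limitations

* Absolute photon fluxes are properties of the full genome-scale
  model's lumped light stoichiometries and are not reproduced by the
  reduced fixture; only the case-2 > case-1 inequality is asserted.
* Proton and charge balancing is not enforced, matching the source
  model's granularity; water is included where the pathway literature
  names it, and carbon/hydrogen balancing of lumped steps is
  deliberately approximate (nitrogen is exact).
* Thermodynamic (ΔG) constraints, loopless FBA and kinetics are out of
  scope; the ammonia-accumulation argument for chlorosis is a verbal
  interpretation layered on the flux results, not a model output.
* The bundled simplex is dense and intended for models up to a few
  hundred reactions; genome-scale inputs parse and validate, but
  solving them wants a sparse industrial LP code.

## A worked session

```{r, eval = FALSE}
model <- build_leaf_fixture()
sol <- solve_scenario(model, leaf_scenario("case1"))
sol$fluxes[c("chl_GluToALA", "mit_GDC", "chl_GOGAT", "chl_Mal2OG_tx")]

run_ammonia_scan(model, "case1", grid = 0:4)
run_gs2_experiment(model, diffusion_enabled = FALSE)
classify_by_variability(run_fva(model, leaf_scenario("case1"),
                                relaxation = 1.5))
reaction_deletion_scan(model, leaf_scenario("case1"))
```
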