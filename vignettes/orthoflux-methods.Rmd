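---
title: "Methods: orthology projection and constraint-based phenotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthology projection and constraint-based phenotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoflux)
```

## The problem

Curated genome-scale metabolic reconstructions exist for only a handful of
organisms, but gene orthology lets one bootstrap a draft reconstruction for
a related species from a curated source: keep the reactions whose
gene–protein–reaction (GPR) rules can still be satisfied by the genes that
have homologs in the target genome, and discard the rest. The draft is then
repaired (gap filling), validated against a battery of producibility tests,
and used for phenotype simulation: single-gene essentiality, and the
subtler question of how a non-lethal knockout redistributes the network's
flux *capacity*.

orthoflux implements that workflow end to end for constraint-based models,
together with a seeded synthetic-reconstruction generator whose every
structural fact is known by construction, so each stage can be tested
against ground truth rather than against another implementation.

## Model representation and GPR semantics

A model is a stoichiometric matrix $S$ (metabolites $\times$ reactions)
with flux bounds $lb \le v \le ub$ (mmol/gDW/hr, $\pm 1000$ by convention),
one objective reaction (biomass, flux $Z$), compartmentalized metabolites
(`base[comp]`, with `e` the extracellular space), subsystem labels, and a
GPR rule per reaction. GPR rules are boolean trees: `or` joins isozymes,
`and` joins complex subunits, `and` binds tighter than `or`, and the empty
rule marks a non-gene-associated reaction, which is treated as always
enabled — spontaneous or orphan reactions survive any gene loss. Reaction
kinds (`exchange`, `demand`, `sink`, `transport`, `biomass`, `metabolic`)
are derived structurally; transport means the same base metabolites move
across compartments without chemical change, which is also what makes base
ids the unit of identity during compartment merging.

Two file dialects are supported and round-trip exactly: a tabular reaction
list (equation strings with compartment suffixes) and SBML Level 2 in the
classic constraint-based style (bounds as kinetic-law parameters,
`GENE_ASSOCIATION`/`SUBSYSTEM` notes); `fbc`-style bound parameters and
gene-product associations are also understood on read.

## Projection

A source gene counts as present in the target species when the homology
table gives it at least one homolog. Each reaction's GPR is evaluated
against that gene set, so an isozyme can rescue a reaction whose partner
gene was lost, and a complex dies with any of its subunits — the only
interpretation under which "reactions linked to genes without homologs"
is well defined for non-trivial rules. Two retention policies are offered:
approach A keeps all non-gene-associated reactions; approach B keeps only
transport, demand, sink, exchange and biomass reactions among them,
dropping orphan pathway reactions. B's reaction set is provably nested in
A's, and projection is monotone: adding homologs never removes a retained
reaction. Retained rules are rewritten into the target namespace by
replacing each leaf with an `or` over its homologs (a gene with two
homologs therefore becomes an isozyme pair, which can change downstream
essentiality — deliberately so, this is what orthologous redundancy means).

Decompartmentalization merges all intracellular compartments into one
cytosol while keeping the extracellular space, because a full merge would
delete every exchange reaction and make growth simulation meaningless; the
full merge is still available behind `keep_extracellular = FALSE` for
topological use. Reactions that cancel (pure intracellular transport) are
dropped; reactions that become identical in stoichiometry and bounds are
merged with the `or` of their GPRs, since either enzyme suffices once
location is lost.

## The flux engine

FBA maximizes $Z$ subject to $S v = 0$ and the bounds; FVA then minimizes
and maximizes each reaction's flux while constraining
$v_Z \ge f \cdot Z^*$. The default fraction is $f = 1$ with an absolute
slack of $10^{-9}$ subtracted from the floor, so solver-tolerance jitter in
$Z^*$ cannot render the fixation infeasible; $f$ is exposed because some
analyses (e.g. capacity comparison around an essential knockout, where the
knockout optimum is 0) are better run with the objective left free.
Reversible reactions are handled natively with signed bounds — no
splitting — and all per-reaction loops run in model order so results are
bit-reproducible.

Linear and mixed-integer programs are solved with the HiGHS solvers in
SciPy, reached through reticulate; the package contains all problem
assembly and the solver is used as a pure LP/MILP oracle. Statuses
(`optimal`, `infeasible`, `unbounded`, `error`) are propagated faithfully
rather than collapsed to zero.

Gene deletion sets the bounds of every reaction whose GPR evaluates false
without the gene to $(0, 0)$. A gene is essential when the knockout
optimum falls below $\varepsilon_{ess} = 10^{-6}$: "zero growth" needs a
numeric cutoff, and $10^{-6}$ sits well above LP feasibility tolerance
(HiGHS defaults near $10^{-7}$) and far below any meaningful growth value.
The same $10^{-6}$ is used to call a reaction FVA-active, for the same
reason.

## Gap filling

Gap filling finds the smallest set of universal-database reactions whose
addition lets the model carry at least $\varepsilon = 1$ flux through a
target: binary indicator $y_j$ per candidate, coupling
$|v_j| \le M y_j$ with $M = 1000$ (the global bound convention, keeping
the MILP numerically benign), minimize $\sum_j y_j$ under steady state of
the combined network. After each optimum an integer cut
$\sum_{j \in Y} y_j \le |Y| - 1$ excludes the found set and the MILP is
re-solved, enumerating alternate solutions of non-decreasing size; a
per-reaction cut variant (forbid every member individually, forcing
disjoint alternatives) is available but non-default, since whole-solution
cuts are what "next-best distinct solution" means. Database reactions
written without compartments are instantiated in the cytosol; a helper
augments any database with one reversible exchange and one reversible
uptake transport per uncovered metabolite, so the search may also open
boundary routes. Solutions are then filtered mechanically: rejected if any
added reaction is the reverse of a forward-only reaction in the model or
database, or lacks the database's organism-evidence flag — the package's
programmatic rendering of a curation step that is otherwise manual.

## Validation and curation

A validation test applies a medium, maximizes a (possibly auto-created and
afterwards removed) demand for a target, and passes at $\ge 10^{-6}$ flux;
every test runs on a fresh copy, so batteries are order-independent. A
target absent from the model is an `error`, not a failure, and tests
flagged compartment-specific are skipped on collapsed models — the flag
must be carried by the battery file because it cannot be inferred from the
target alone. The curation loop diagnoses each failing test by searching
the projection's removed-reaction pool for a minimal restoration (single
reactions first, then pairs, capped at $10^4$ pair evaluations — the
manual process this mechanizes is unbounded, a tool must not be), restores
the candidates, and repeats; the pass fraction is non-decreasing and the
loop ends at 100% or with the unresolvable tests reported.

## Knockout phenotype statistics

Comparing knockout and wild-type FVA, each reaction's capacity change is
classified by the shift in its maximal flux $v_{max}$: decreased,
unchanged, or increased, with a relative tolerance of $10^{-6}$ and an
absolute floor of $10^{-9}$ so LP noise cannot generate spurious counts.
Classification on the full range width is provided as a non-default
variant. Per major subsystem, the decreased/increased counts are tested
against even probability with the 1-df goodness-of-fit statistic
$$X^2 = \frac{(n_{down}-E)^2}{E} + \frac{(n_{up}-E)^2}{E}, \qquad
E = \frac{n_{down}+n_{up}}{2},$$
no continuity correction, upper-tail p-value, $p = 1$ at zero counts.
Significance uses $\alpha/k$ with $\alpha = 0.05$ and $k = 10$ independent
subsystem tests, and summaries of "significant metabolism subsections"
exclude the Transporters subsystem, which is a logistics category rather
than a metabolism subsection. Activity profiles (active/inactive per
reaction over a shared universe, absent reactions inactive) are related by
Jaccard distance and average-linkage clustering with label-sorted
deterministic tie-breaking; distance and linkage are stated in the output
because nothing in the method prescribes them.

## The synthetic generator

The generator emulates the structure such a pipeline must survive, not the
chemistry: per biomass precursor, a linear chain (exchange, reversible
uptake transport, then conversions routed through random intracellular
compartments, ending in the cytosol) feeds a single biomass reaction; GPR
rules are drawn per conversion as isozyme pair / complex pair / non-gene /
single gene with configurable fractions; a configurable number of chains
gets a parallel duplicate path (making their genes provably non-essential);
blocked reaction pairs plant flux-dead appendices and dead-end metabolites.
Every second conversion co-produces a byproduct with its own demand
outlet, and each precursor also gets a demand; biomass consumes precursors
at coefficient 0.5, so at the fixed optimum each chain retains capacity
headroom and the network's chains stay observable independently of biomass
— without those outlets, one broken chain would drag every other chain's
capacity to zero through the common biomass sink and per-subsystem shift
statistics would be degenerate by construction.

Ground truth is recorded as it is built: essential genes (single-gene or
complex rules on single-path chains), reaction kinds, subsystem labels
(the ten major-subsystem names, round-robin per chain, transports and
exchanges under Transporters), blocked reactions, dead ends, per-test
dependency sets, and media (a rich medium plus one minimal medium per
chain). The default scale — 10 chains of 8 conversions in 3 intracellular
compartments, roughly 170 reactions and 110 genes — is large enough to
exercise compartment routing and all reaction kinds while keeping
exhaustive oracles (truth tables, vertex enumeration, subset enumeration)
and the LP batteries fast; tests that need other regimes (e.g. a
300-gene homology table for binomial retention bounds, or all-single-gene
chains for the bottleneck property) construct their own spec.

What the generator does *not* emulate — and what passing on it therefore
does not show about real reconstructions: mass- and charge-balanced
stoichiometry, shared currency metabolites and cofactor coupling, loops
and thermodynamically infeasible cycles, wide GPR rules with nested
structure, and realistically uneven subsystem sizes. Conclusions about
solver-scale behaviour on curated mammalian models (thousands of
reactions) also do not follow from these problem sizes.

## Degenerate inputs and tie-breaks

Empty GPRs evaluate true; an empty homology table projects to exactly the
non-gene-associated reactions (approach A). Zero-count subsystems get
$p = 1$. A gap-fill call on an already-feasible target returns one
zero-addition solution. Media list every open exchange explicitly;
unlisted exchanges are closed for uptake and left open for secretion at
the default bound, and re-applying a medium is idempotent. Identical FVA
profiles produce a zero-height tree; ties in clustering are broken by
label order. All generator functions take explicit seeds and restore the
caller's RNG state.

## Known limitations

Gap filling treats directionality evidence and organism evidence as
database flags, not as inferences; the curation search is capped at pairs;
the pipeline is single-threaded by design (determinism over speed); and
SBML support targets the two constraint-based dialects described above,
not arbitrary SBML.
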