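---
title: "Testing rival species-tree hypotheses by deep-coalescence bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing rival species-tree hypotheses by deep-coalescence bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The North American admiral butterfly *Limenitis arthemis* comprises three
lineages: two Batesian mimics of *Battus philenor* (*L. a. astyanax* and
*L. a. arizonensis*) and the non-mimetic, white-banded *L. a. arthemis*.
Two rival accounts of wing-pattern evolution correspond to two rival
species trees for these lineages:

* **Reversion hypothesis (R)** — mimetic *astyanax* is sister to
  non-mimetic *arthemis*: mimicry arose once in the ancestor of all three
  lineages and was subsequently lost in *arthemis*.
* **Monophyletic-mimic hypothesis (MM)** — the two mimetic lineages
  (*astyanax* + *arizonensis*) form a clade: mimicry arose once and was
  never lost.

Because gene trees estimated from single loci disagree with each other —
incomplete lineage sorting and post-glacial hybridization both generate
gene-tree/species-tree discordance — picking the best-scoring tree is not
enough. `dcboot` instead asks, for an explicit demographic model built
around either species tree: *would data generated under this model look
like the data we observed?* That is a parametric bootstrap: simulate many
multi-locus replicates under the model, score each replicate exactly as
the observed data were scored, and locate the observed statistics in the
simulated distributions.

## The statistics

Both statistics derive from the **minimum number of deep coalescences**
(Maddison's "extra lineages"): fitting a rooted gene tree into a rooted
species tree, the minimum over all valid coalescent histories of the
number of gene lineages beyond one that each species-tree branch must
carry. The package computes it cluster-wise: for the species cluster $C$
below a species-tree edge, $k(C)$ is the number of maximal gene-tree
clades whose tips map entirely into $C$, and the edge contributes
$\max(0, k(C) - 1)$. Tip edges are included, so multiple alleles of one
species are handled; species missing from a locus contribute nothing;
branch lengths are ignored (the statistic is topological). A brute-force
oracle (`brute_force_deep_coalescences()`) enumerates coalescent
histories directly and is tested to agree exhaustively on small
instances.

For a set of loci:

* `summed_dc()` — the total count over loci on one species tree, the
  *absolute* fit of the data to that hypothesis;
* `delta_statistic()` — the *relative* fit
  $\delta = \mathrm{dc}(T_R) - \mathrm{dc}(T_{MM})$, negative when the
  reversion tree fits better.

For the eight observed nuclear loci (four coding: EF1a, wingless,
kettin, Ldh; four anonymous) the observed values are 93 deep
coalescences on the reversion tree, 108 on the monophyletic-mimic tree,
$\delta = -15$. These are carried by `limenitis_observed()`; the sums can
also be recomputed from newick files with `observed_from_trees()`.

## The demographic models

`limenitis_models()` builds fifteen structured-coalescent models over the
six North American lineages (the three *arthemis*-complex lineages plus
*L. archippus*, *L. lorquini*, *L. weidemeyerii*):

* twelve MM models: three choices of the *arthemis* divergence time
  $T_2$, each with two choices of the *astyanax*/*arizonensis* split
  $T_1$, under two migration tiers (MM1–MM6 moderate, MM7–MM12 high);
* three R models differing only in the *arthemis*/*astyanax* split $T_1$.

Shared parameters, with units:

| parameter | value | unit |
|---|---|---|
| contemporary effective sizes | 2.5 × 10⁶ | diploid individuals |
| *arthemis*-complex stem size | 3.5 × 10⁵ | diploid individuals |
| generations per year | 2 | — |
| hybridization window | [0, 12 000) | years before present |
| moderate migration | 3.2 (*astyanax*→*arthemis*), 0.14 (reverse) | see below |
| high migration | 17.71, 15.53 | see below |

Simulation happens on the coalescent scale (`to_coalescent_scale()`):
time in units of $4 N_\mathrm{ref}$ generations ($N_\mathrm{ref}$ =
2.5 × 10⁶), deme sizes as ratios to $N_\mathrm{ref}$, and forward-time
migration of $M$ migrants per generation into a deme of size $N$ as a
backward per-lineage rate of $4 N_\mathrm{ref} M / N$ per scaled unit.
Sampling per locus follows the study's per-lineage allele counts
(`limenitis_sampling()`); loci are simulated independently.

### The migration-rate convention

The published migration estimates (3.2/0.14 and 17.71/15.53) come from a
coalescent-likelihood analysis whose output scale is ambiguous: they may
be expected migrant individuals per generation ($Nm$) or already
coalescent-scaled rates in the `ms` convention ($4 N_0 m$). The two
readings differ by a factor of four here. We calibrated the choice
against the published per-model simulated means: under the $Nm$ reading
the high-migration models show roughly fourfold stronger introgression
than the published table (e.g. MM7's mean $\delta$ falls below zero,
where the published value is 5.14), while under the $4 N_0 m$ reading all
fifteen per-model means are reproduced within Monte-Carlo error. The
builtin models therefore default to `migration_unit = "scaled_4Nm"`; the
literal reading remains available as
`migration_unit = "migrants_per_gen"`, and every report records which
was used.

### Outgroup configuration

The three outgroup divergence times are not published. They enter as
configuration: a ladder of successive joins onto the *arthemis*-complex
stem — *lorquini*, then *weidemeyerii*, then *archippus* — with defaults
1.5, 2.5 and 3.5 Myr, all older than every ingroup divergence. We
parameterize the outgroup arrangement as this ordered ladder (rather
than an arbitrary newick string) because each join needs its own time
and only ladders arise from successive stem joins; the order and times
are arguments of `limenitis_models()` and of the run configuration.
$\delta$ is driven by the ingroup and is insensitive to these choices,
but the *absolute* deep-coalescence level is not: with our defaults the
simulated mean counts sit a few percent below the published ones
(roughly 5–10 units over eight loci), uniformly across models. Users
comparing absolute counts should treat the outgroup times as parameters
to vary, not constants.

The ancestral stem of the *arthemis* complex keeps the published reduced
size (350 000) from the older ingroup split back to the *lorquini* join;
all other ancestral demes default to the contemporary size, since no
other ancestral estimate is published.

## The bootstrap test

`evaluate_model()` simulates `nreps` eight-locus replicates under one
model, computes per replicate the two summed counts and $\delta$, and
returns both empirical tail probabilities for each statistic:
$p_\mathrm{low} = \#\{ \mathrm{sim} \le \mathrm{obs} \}/n$,
$p_\mathrm{high} = \#\{ \mathrm{sim} \ge \mathrm{obs} \}/n$ (ties count
in both tails, so $p_\mathrm{low} + p_\mathrm{high} = 1 + \mathrm{ties}/n$;
zero tails are reported as "< 1/n"). The deep-coalescence criterion uses
the model's own topology — the MM tree for MM models, the R tree for R
models. The default `nreps = 2000` makes the smallest resolvable nonzero
tail 0.0005, the granularity visible in the published table.

A model is **supported** when the observed value of *both* statistics is
unremarkable under the model. Two operationalizations are provided:

* `support_rule = "tail"` (default): minimum tail ≥ α (= 0.05). This
  reproduces the published decisions exactly, including the borderline
  rejections of models whose minimum δ tail was 0.0255 and 0.025.
* `support_rule = "central"`: observed inside the central 95% interval
  (minimum tail ≥ α/2), the literal "within the 95% distribution"
  reading. Under this rule those two borderline models would flip to
  supported.

We report both tails and the minimum rather than a single
direction-switching p-value.

`run_model_suite()` runs `evaluate_model()` for a list of models with
independent seed substreams and summarizes one row per model;
`run_full_analysis()` wraps the whole pipeline behind a single YAML/JSON
config and writes a report (TSV + JSON with provenance: seed, parameter
values, config fingerprint), the raw simulated distributions, and a log.

## Simulator numerics

The simulator is an event-driven continuous-time structured coalescent
(compiled core): within a deme of relative size $x$ each lineage pair
coalesces at rate $2/x$ per scaled unit; migration phases contribute
per-lineage backward rates; waiting times are exponential races, and
epoch boundaries (splits, phase starts/ends) partition time into
constant-rate intervals — jumping to a boundary and redrawing is exact
by memorylessness. At equal event times splits are applied before
migration-phase toggles, so event ordering is deterministic. A model in
which some lineages can never reach a common ancestor raises an error
rather than spinning.

All randomness flows through R's Mersenne-Twister; `set.seed(seed)`
fully determines every output, file and report. Per-locus seeds are
derived from a replicate seed by locus index (and per-replicate seeds
from the run seed) through a small integer map, so any locus or
replicate can be regenerated in isolation and runs parallelize without
sharing streams. Identical seeds give byte-identical newick files and
reports; every report embeds enough provenance to regenerate itself.

Branch lengths are emitted in coalescent units (tips at 0, ultrametric);
`units = "years"` rescales by $4 N_\mathrm{ref} / (\text{generations per
year})$ for diagnostics. Reconciliation ignores lengths entirely.

## Synthetic data: what it does and does not emulate

`generate_pseudo_observed()` writes one simulated replicate in exactly
the observed-data input format (eight newick files, a taxon-map TSV, a
JSON manifest with the model fingerprint and seed), so the entire
pipeline is exercisable with no external data; the files regenerate
bitwise from (model, seed). `degrade_to_consensus()` additionally
collapses a chosen fraction of the shortest internal branches into hard
polytomies, mimicking the loss of resolution of consensus trees (a
fully collapsed tree keeps a polytomous root; pass `assume_rooted =
TRUE` to count on such trees).

The generator reuses the simulator — by design, since the structured
coalescent *is* the assumed data-generating process; independence for
validation comes from the brute-force reconciliation oracle and from
closed-form coalescent expectations (mean pairwise coalescence time 0.5,
mean 10-sample TMRCA 0.9 scaled units). What the synthetic data do *not*
emulate: mutational noise and gene-tree estimation error (trees are true
simulated topologies, not re-estimated from sequences), gene-tree
uncertainty, intra-locus recombination, and selection. Passing tests
therefore validate the simulation-and-scoring machinery under the
model's assumptions, not the robustness of the biological conclusion to
estimation error.

## Problem sizes and test design

The test suite runs the suite comparison at 500 replicates per model
(tail granularity 0.002) and the recovery experiment at 20 pseudo-
observed data sets × 500 replicates; the acceptance script uses the full
2000. Reconciliation is verified against the oracle exhaustively over
all 945 rooted six-tip gene-tree topologies for several allele
configurations and on 200 random 7–8-tip instances. The recovery
experiment evaluates support under the `"central"` rule, whose joint
type-I error for the two (correlated) statistics is the quantity the
≥ 90% recovery expectation presumes; the stricter `"tail"` rule trades
~5 points of recovery for reproducing the published decisions.

## Known limitations

* Gene trees with fewer than two sampled alleles at a locus are
  rejected; the observed design always has ≥ 23.
* The deep-coalescence counter supports at most 64 species (bitmask
  core) — far above the six needed here.
* Consensus-tree polytomies are treated as hard; no search over
  resolutions is attempted, matching how the observed consensus trees
  were scored.
* Migration phases must fall within the lifetimes of both demes; the
  builtin window (0–12 kyr) trivially satisfies this.
* Absolute deep-coalescence levels depend on the unpublished outgroup
  times (above); conclusions should rest on $\delta$ and on relative
  comparisons unless those times are known.
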