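---
title: "Mining and explaining drug side-effect profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and explaining drug side-effect profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepminer)
```

## The problem

Adverse-effect annotations on drug package inserts are redundant
(many MedDRA-style terms describe near-identical clinical pictures)
and strongly co-occurring (a drug that causes headache often also
causes abnormal sensations). Studying side effects one term at a time
therefore both fragments the signal and ignores its correlation
structure. `sepminer` takes the opposite route: it compresses the
term vocabulary into semantically coherent **term clusters** (TCs),
mines **side-effect profiles** (SEPs) — the largest TC combinations
shared by a substantial fraction of the drug set — and then asks what
drug and target properties explain membership in each profile, using
two deliberately interpretable model families.

This vignette records the package's model choices, parameters and
their defaults, the numerical conventions, what the synthetic
generator does and does not emulate, and known limitations.

## Term similarity and clustering

**Similarity.** Side-effect vocabularies are rooted DAGs (a term may
have several parents, via `is_a` and `part_of`). We use a Wu–Palmer
similarity generalized to DAGs:

$$ sim(a,b) \;=\; \max_{c \,\in\, anc(a)\cap anc(b)}
   \frac{2\,d(c)}{d(a)+d(b)} $$

where ancestors include the terms themselves, both relation types
count as hierarchy edges, and $d(\cdot)$ is the shortest edge count
from the nearest root. The measure is purely structural — it needs no
corpus statistics, only the hierarchy — which is the property we
require of a term-vocabulary similarity. Conventions for degenerate
inputs: $sim(a,a)=1$ even for roots (where the ratio is 0/0), and two
terms whose only common ancestor is a root score 0. Alternative
information-content measures would need annotation frequencies and are
deliberately out of scope.

**Clustering.** Distances $1 - sim$ are agglomerated by Ward's
method, computed via the Lance–Williams recurrence on squared
distances (`stats::hclust(method = "ward.D")` on $d^2$); merge
heights are therefore in squared-distance units and non-decreasing.

**Cut selection.** The number of clusters is chosen by the
Kelley–Gardner–Sutcliffe penalty: at each level with $k$ clusters
($2 \le k \le n-1$) the average spread is the mean, over clusters of
size ≥ 2, of the mean within-cluster pairwise distance; spreads are
min–max normalized onto $[1, n-2]$ and $k$ is added; the minimizing
level wins. Two conventions matter in practice and are fixed here:
ties go to the **smaller** $k$ (coarser, hence more interpretable,
clusters), and when all spreads are equal the normalization is
degenerate and all levels get normalized spread 1 — the penalty then
reduces to $1 + k$ and correctly selects the coarsest cut. Users can
override the cut with an explicit `k`; a real MedDRA/insert corpus in
the hundreds-of-clusters regime is expected to be cut by expert
judgement as much as by the penalty.

**Naming.** Each cluster is indexed in dendrogram (leaf-order) of the
tree and named `index_Representative`; the representative is the
cluster medoid (maximal mean similarity to co-members), ties broken
by the lexicographically smallest label. The medoid rule is our
choice; any fixed, deterministic rule would serve.

## Fingerprints: associating drugs with TCs

Cluster sizes vary widely (singletons to dozens of terms), so a fixed
count of matching terms would be either too loose for large clusters
or too strict for small ones. The association threshold grows with
cluster size in steps of five:

$$ n_i \;=\; \min(5,\ \lceil k_i / 5 \rceil) $$

so sizes 1–5 need one matching term, 6–10 two, …, 21 and above five.
`interval_width` and the cap `n_max` are configurable
(`assoc_config()`); the defaults are the published operating point of
the procedure. Terms annotating a drug but missing from the
clustering's universe are skipped and counted (`skipped_terms`
attribute) — real vocabularies drift and a hard error would be wrong.

TCs covering **more than** half of the drugs (strictly) are removed
before mining: near-universal clusters carry no discriminative signal
and blow up the itemset lattice. Exactly 50 % is kept.

## Profile mining

A SEP is a **maximal frequent itemset** of TCs: frequent means shared
by at least `min_support` drugs (default: 20 % of the drug set,
`ceiling(0.2 * n)`; an absolute override exists because the two
published formulations — "more than 100" and "at least 20 % (110)" —
differ, and we follow the one consistent with the published profile
table). Maximality means no frequent proper superset, which implies
an anti-chain and the useful bound that two distinct SEPs are jointly
contained in fewer than `min_support` drugs.

The miner is a depth-first search over the itemset lattice with
tidset intersection for support counting and a superset check against
already-found MFIs; any correct MFI algorithm is acceptable, so the
contract is oracle equivalence: `brute_force_mfis()` enumerates all
$2^m$ itemsets (refusing $m > 20$) and the test suite asserts set
equality on hundreds of random tables. Output order is fixed —
support descending, then lexicographic TC sets — so SEP identifiers
are reproducible; the published table's ordering rule is not stated,
and ours is a convention.

One caveat discovered while testing: raising the support threshold
does *not* shrink the union of covered drugs (shorter maximal
itemsets cover more drugs each); what is monotone, and what the tests
assert, is that every higher-threshold MFI is contained in some
lower-threshold MFI and covers a superset of its drugs.

## Learning sets

For a SEP, positives are drugs whose fingerprint contains **all** its
TCs and negatives are drugs showing **none** of them; partial matches
are excluded from both classes. This deliberately asymmetric rule
reflects that absence of an annotation is weak evidence — a drug with
half a profile is neither a clean positive nor a trustworthy
negative.

## Decision trees

`learn_tree()` is a C4.5-style learner specialized to the binary
attribute tables produced here (`build_attribute_table()`: category
indicators, three action indicators per target, cluster-membership
indicators). Splits are binary value-vs-rest tests chosen by **gain
ratio** among candidates leaving at least `min_leaf = 5` rows in each
child; ties go to the earliest column, then earliest value; for
two-valued attributes the test value is the larger one so trees read
`attr == 1`. Pruning is bottom-up pessimistic-error pruning with the
C4.5 binomial upper bound at confidence `cf = 0.25`
(`qbeta(1 - cf, E + 1, N - E)`); subtree raising is omitted — at the
table sizes involved its effect is marginal and it would substantially
complicate the implementation. Missing attributes at prediction time
take the not-equals branch. Exact numerical replication of another
C4.5 implementation's pruning decisions is a non-goal; the contracts
are the split criterion (asserted against hand-computed entropies),
the leaf-size floor, determinism, and perfect resubstitution on
separable data when unpruned.

## Relational rule induction

The relational learner is Progol-style: a **bottom clause** is built
from a seed positive by breadth-first instantiation of mode
declarations (`default_modes()` encodes the rule language: drugs chain
to targets, targets to interactants, proteins to GO/pathway/domain
annotations, GO terms along `is_a`/`part_of` edges; labels may be
constants, drug and protein arguments are always variablized), capped
at `saturation_cap = 50` literals per predicate and `max_chain_depth
= 3` entity steps. Rule search is a beam search (width 20) over
bodies that are subsets of the bottom clause, grown one connected
literal at a time. A rule is acceptable when it covers at least
`min_pos = 5` positives and at most `noise = 1` negatives **of the
full training sets**; among acceptable rules the one maximizing P
wins, ties to fewer literals, then discovery order. The beam is
prioritized by the coverage score $P - N$: prioritizing raw $P$ makes
the beam fill with vacuous refinements (adding an unconstrained
chain literal never reduces coverage), which starves genuinely
discriminative bodies — the coverage score is the standard remedy.
Anti-monotonicity of coverage justifies two prunes: refinements below
`min_pos`, and refinements that cannot beat the current best rule's P.

`induce_cover()` iterates seeds in the fixed input order of the
positives, removing covered positives from **seed selection only**:
accepted rules may overlap in coverage and P/N are always measured on
the full sets. This is our reading of induce-cover semantics
("overlapping rules are produced"); the alternative —
re-scoring against residual positives — would produce disjoint
covers, contradicting that description. A theory predicts positive
when any rule covers the drug.

The coverage of a candidate body over the example set is evaluated as
a relational semi-join over the fact tables (vectorized, projecting
onto the head variable and the variables still needed downstream)
rather than per-drug backtracking; single-drug checks (`covers()`)
use an indexed depth-first engine with first-argument indexing.
Query evaluation is guarded by a configurable result cap (default
$10^6$ bindings).

## Evaluation

`stratified_cv()` runs `runs = 10` × `folds = 10` stratified
cross-validation: per run each class is shuffled with a run-specific
seed (`seed + run − 1`) and dealt round-robin into folds, so fold
class sizes deviate from the proportional target by at most one, with
remainders going to the first folds. Models are retrained inside
every fold; confusion matrices come from held-out predictions only.
Accuracy, specificity and sensitivity with zero denominators are
reported as `NA`, never as zero. Summaries are means (and standard
deviations) over the 100 assays.

`direct_test()` labels held-out drugs by the learning-set rule
(partial profile matches are skipped) and returns the false-positive
drugs, which `faers_check()` then screens: a drug is confirmed when,
for **every** TC of the SEP, at least one report names it as primary
suspect of a term inside that TC — reports with any other role never
confirm. The check is an anticipation device: insert updates lag
spontaneous reports, so a "false positive" with consistent
primary-suspect reports is plausibly a true positive not yet on the
insert.

## The synthetic generator

`synth_scenario()` emulates the joint structure of the real inputs:
a rooted DAG term hierarchy (full b-ary `is_a` tree, 10 % of terms
given a second `part_of` parent), 300 drugs averaging four targets
each (Poisson-shifted), annotation-rich proteins (GO terms with a
random DAG of relations, pathways with source labels, domains,
protein–protein interactions), drug categories and method-tagged
structural clusters. Planted rules are instantiated with *dedicated*
fresh entities per carrier and reserved constants, and the generator
verifies that exactly the carriers satisfy each body, failing
otherwise. Carriers receive the minimal required terms of every TC of
their rule's profile (with probability $1-fn$; non-carriers with
probability $fp$); background annotations are drawn at rate 0.02 from
terms **outside** all planted profiles so that, in the noise-free
setting, fingerprint positives are exactly the carriers — a sharp
ground truth for end-to-end tests. Every generator stage derives its
RNG stream from the master seed, so identical configurations export
byte-identical files.

What the generator does **not** emulate: realistic GO/pathway size
distributions, term-frequency skew, correlated annotation errors,
chemical-structure-driven cluster memberships, or the published entity
counts. Green tests therefore demonstrate correctness of the
machinery — recovery of signals that are present by construction —
not performance on real pharmacological data.

Problem sizes used by the test suite were chosen to exercise every
code path at desk scale: the reference synthetic study uses 300 drugs
with two relational rules and one category rule; module tests use an
80-drug variant; miner oracle equivalence runs on 200 random 100-row
tables with up to 12 columns; the profile-overlap bound is checked on
twenty 554 × 99 tables at support 101.

## Known limitations

- The semantic similarity is a stated structural substitute for
  whatever level-weighted measure a licensed MedDRA pipeline might
  use; no claim of equivalence is made, and the published
  112-cluster operating point is not a target (it depends on the
  licensed vocabulary and corpus).
- The rule search is a beam search: it is deterministic and recovers
  planted rules in the tested regimes, but offers no completeness
  guarantee for adversarial knowledge bases.
- Cross-validating the relational learner retrains it 100 times; on
  large knowledge bases this is the dominant cost and is left to the
  user's batch budget (the pipeline's `cv` flag defaults to off).
- The "average overlap" column of the packaged reference profile
  table is parsed but not recomputed; its definition is not public.
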