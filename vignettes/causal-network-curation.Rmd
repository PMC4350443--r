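---
title: "Curating causal biological networks: models, statistics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating causal biological networks: models, statistics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belnet)
```

# The curation model

`belnet` supports the life cycle of causal biological network models of
the kind used to describe disease signaling (our running example is early
chronic obstructive pulmonary disease, COPD). A model is a graph whose
nodes are typed biological entities written in a restricted Biological
Expression Language (BEL) dialect and whose edges are causal statements
(`increases`/`decreases`) or non-causal self-links (a protein connected
to its own activity), each backed by one or more evidence records: a
citation, quoted supporting text, and the experimental context (species,
tissue, cell type, disease, exposure) in which the finding was made.

Construction proceeds in phases, and every edit carries provenance naming
its phase: the non-diseased starting scaffolds (`phase0_nondiseased`),
literature- and data-driven disease enhancement (`phase1_literature`,
`phase1_rcr`), open crowd verification (`phase2_crowd`), and the expert
jamboree (`phase3_jamboree`). Networks are immutable values: every
mutating operation returns a new network with the revision incremented by
exactly one and one history row appended, so the full revision history is
reconstructible. Deletions never happen physically; evidence that a crowd
rejects is retained with status `rejected`.

## BEL dialect and canonicalization

A term is a function prefix applied to namespaced entities, nested terms,
or (under `pmod`, `tloc`, `sub`, `trunc`, `fus` only) plain qualifier
tokens. The function and namespace registries ship as two-column data
tables rather than code, because namespace vocabularies evolve (one of
the packaged namespaces is explicitly provisional); users can extend them
or supply replacement TSVs. Prefix matching is case-sensitive and no
fuzzy matching is attempted: in a crowd setting, silent repair of an
unknown prefix would corrupt node identity.

Node identity is the *canonical key*: the serialized term after
canonicalization. Whitespace never matters; names with spaces or colons
are double-quoted in text and stored verbatim; and the arguments of
`complex`/`composite` are sorted lexicographically (byte order, so the
result is locale-independent), because a complex of STAB1 and STAB2 is
the same node no matter the written order. All other functions keep
argument order, which is positional (`pmod(P,S,273)`). Nesting is capped
at depth 4 — deeper terms are in practice transcription errors. Edge
identity is the canonical statement string; adding an existing statement
appends its evidence instead of duplicating the edge.

# The RCR scoring engine

The data-driven enhancement phase asks: which upstream mechanisms, taken
from a causal knowledgebase of signed mechanism-to-gene effects, explain
an observed differential-expression profile?

**State changes.** A gene is a state change when `fdr_p < 0.05`,
`|fold change| >= 1.3` (linear scale; a flag converts log2 input) and
`mean expression >= 100` (array intensity units). The FDR cutoff is
strict and the other two inclusive, so a gene sitting exactly at
(0.049, 1.3, 100) passes. These defaults are the enhancement protocol's
stated thresholds; all three are configurable.

**Tails.** For a hypothesis with `m` downstream genes in a universe of
`N` measured genes, `n` state changes and overlap `k`, richness is the
hypergeometric upper tail `P(X >= k)`; concordance is the binomial
fair-coin upper tail `P(Y >= c)` over the `k` overlapping genes, `c` of
which moved in the predicted direction. Both return exactly 1 at zero
overlap. The protocol we implement names the cutoffs (richness p < 0.1,
concordance p < 0.1) but not the tail formulas, which live in the
original reverse-causal-reasoning method; we fix the standard
definitions — hypergeometric and binomial(1/2) upper tails — and expose
them as plain functions (`richness_p()`, `concordance_p()`) so an
alternative scoring rule can be substituted. No multiple-testing
correction is applied across hypotheses: the cutoffs are deliberately
raw, matching the protocol, because downstream every candidate is vetted
by a human curator rather than reported as a discovery.

**Universe.** The default universe is all measured genes
(`measured_genes`), since state-change rates depend on the platform; a
`kb_covered_genes` policy restricts to genes any hypothesis covers, for
sensitivity analysis. Knowledgebase entries listing the same gene with
both signs under one hypothesis are contradictory and dropped from that
hypothesis with a warning count. Scores are computed for the
knowledgebase-stated orientation only (concordant means the observed
direction equals the stated sign); the opposite mechanism is its own
knowledgebase entry. Ties in the output ordering are broken by
concordance p and then by upstream canonical key, so results are
deterministic.

**Proposals.** Significant mechanisms whose upstream term is not yet a
node are turned into candidate edges toward a curator-designated anchor
process node, with relation `increases` when the net predicted direction
is up. Candidates carry `phase1_rcr` provenance and open status and are
never merged automatically — connecting a predicted mechanism into the
right place of the right network is a curation act.

# Crowd verification

Votes arrive as a chronological ledger. Each user holds one effective
vote per evidence, a later vote superseding the earlier (the underlying
platform's revote behavior is unspecified; supersession is our declared
choice). After every vote the effective tallies are re-evaluated: four
effective up-votes lock the evidence `approved`, four effective
down-votes lock it `rejected`, and the first threshold crossed wins —
this per-vote evaluation resolves what happens on ledgers that would
eventually reach both thresholds. Locked evidence refuses further votes.
Summary totals count *raw cast* votes, not effective ones, matching how
aggregate voting activity is conventionally reported.

Leaderboard points per action default to new evidence 5, new edge 5, new
node 2, vote 1. The exact point values of the original platform are
unpublished; these are declared package constants, overridable, and the
scheme used is recorded on every leaderboard. The jamboree invitation
rule — among users with at least 20 votes, the top 20 by evidences
created — is implemented as `jamboree_invitees()`.

# Agglomeration

Before crowd review, related networks are merged per a specification
(each group of ≥ 2 sources yields one target; every source must be
covered exactly once), and edge variants are collapsed: edges sharing a
subject, a downstream gene and a causal sign but differing only in the
object's molecular form (`p(X)`, `r(X)`, `g(X)`, `sec(X)`) become one
representative edge carrying the union of evidences and an annotation
listing the collapsed forms. The survivor preference protein > RNA >
gene > secretion is our convention (the protocol states that these
variants were agglomerated but not which form survives); protein is the
most commonly verified form. Nested objects such as `act(p(X))` are
never family-eligible. Evidence counts are conserved by both operations,
and edge collapsing is idempotent.

# I/O

The BEL-script dialect is line-oriented: `SET Document Name/Description`
headers, then per evidence a `SET Citation` (which starts a fresh
evidence block), `SET Evidence`, optional context `SET`s, and statement
lines. Evidence identity is the hash of citation, quote and statement,
so two statements under one block get distinct ids. XGMML export writes
one node element per node (label = canonical key, shape by function
class: activities triangles, processes/pathologies diamonds,
translocations rounded squares, proteins squares, other abundances
circles — the convention of the model set's published figures) and one
edge element per edge (interaction = relation, evidence count as an
attribute); elements are emitted in sorted order so export is
byte-deterministic. Import is structure-only: labels that fail BEL
parsing are retained as opaque nodes flagged `unparsed` rather than
dropped. Evidence metadata beyond counts stays in the BEL script; XGMML
targets graph viewers.

# The synthetic-data generators

All tests and the acceptance script run on generated inputs; nothing is
downloaded.

`sim_rcr_fixture()` emulates a disease-versus-control transcriptomics
comparison: 1000 measured genes (synthesized in the numeric EGID
namespace, so no claim is made about real genes), a 20-hypothesis
knowledgebase with 20 signed targets each, one planted mechanism with 18
of its targets flipped concordantly, and a background state-change rate
of 0.033 so that roughly 50 genes change state in total. Those defaults
are the package's stated study conditions: they produce a signal that
passes the 0.1/0.1 cutoffs with wide margin while decoy hypotheses pass
only rarely. The expression table is constructed so that exactly the
generated state changes pass the selection thresholds, with every
non-state-change row failing one predicate chosen at random — which also
exercises each predicate's boundary. Truth records are computed at
generation time by direct combinatorial summation (explicit
`choose()`-based tails), never by the scoring engine under test.

What the generator does *not* emulate: real expression distributions,
correlated genes, platform normalization or batch structure, overlapping
hypothesis target sets with realistic topology, or voter behavior. A
passing recovery test therefore demonstrates the statistical machinery
and its thresholds, not performance on real microarray data.

`sim_vote_ledger()` realizes configured up/down tallies under chosen
interleavings with a distinct user per vote; `sim_vote_totals()` spreads
aggregate totals over evidences in a never-locking pattern (at most 3 up
and 3 down per evidence) so that every configured vote is actually
counted. `sim_version_pair()` grows a base network by scripted node,
edge and evidence additions whose expected diff is known by
construction. All generators restore the caller's RNG state and are
byte-deterministic under a fixed seed.

# Numerical and testing choices

Tails are computed via `phyper`/`pbinom` (stable log-space
implementations); tests compare them against two independent oracles —
explicit combinatorial summation over every `(k, n, m, N)` with
`N <= 20` at 1e-12, and literal enumeration of all draws at small sizes.
Vote locking is validated against a brute-force oracle that recomputes
effective tallies from scratch at every ledger prefix, on 10,000 random
ledgers including supersession and first-crossing checks. Round-trip
suites cover 10,000 generated terms (parse-serialize identity) and
1,000 generated networks (XGMML graph isomorphism with equal labels).
Recovery statistics use 200 seeded fixtures; these problem sizes keep the
whole suite in the low minutes on one CPU while leaving the assertions'
margins wide. Percent shares are rounded half away from zero to integers
(base `round()`'s round-half-even would report 46.5% as 46, not 47,
which does not match curation bookkeeping style); an all-zero total
yields an undefined (`NA`) share rather than 0.

# Known limitations

- The dialect covers the constructs used in curated disease network
  sets, not the full openBEL grammar (no annotation DSL, statement
  lists, or nested statements as objects), and no orthology mapping
  between HGNC/MGI/RGD identifiers is attempted.
- Boundary-condition matching is exact-string and case-insensitive
  against configured lists; there is no ontology expansion, so "NSCLC"
  does not match an excluded "lung cancer".
- The mapping of many predicted mechanisms onto fewer curated edges is a
  human act; `propose_enhancements()` emits one candidate per mechanism
  and leaves consolidation to the curator.
- XGMML import is structure-only; evidence text does not survive a
  BEL-to-XGMML-to-BEL trip, by design.
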