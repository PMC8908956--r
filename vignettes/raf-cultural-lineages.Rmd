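---
title: "RAF networks and cultural lineages: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RAF networks and cultural lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rafnet)
```

## The model

A *catalytic reaction system* (CRS) is a tuple Q = (X, R, C, F): element
types X, reactions R (multisets of reactants and products drawn from X),
a catalysis assignment C recording which element types catalyse which
reactions, and a foodset F ⊆ X of elements present from the outset.  A
non-empty reaction subset R′ ⊆ R is a *RAF* — reflexively autocatalytic
and F-generated — when

1. every reaction in R′ has at least one catalyst in F or among the
   products of R′ (reflexive autocatalysis), and
2. every reactant of every reaction in R′ is reachable from F using
   only reactions of R′ (F-generated).

RAF theory originated in origin-of-life research, where elements are
molecules; the same formalism applies to conceptual networks, where
elements are *mental representations* (MRs), the foodset holds MRs that
are innate or acquired by social or individual learning, reactions are
mental operations such as concept combination, and catalysts are the
needs, desires and pieces of knowledge that spark those operations.  A
RAF in a conceptual network is a self-sustaining body of mutually
accessible ideas: from the foodset there is a catalysed stream of
thought culminating in each of its members.

If a CRS has any RAF it has a unique maximal one, the **maxRAF**,
because the union of two RAFs is again a RAF (availability is set-based
and monotone, so both defining conditions survive unions).  `max_raf()`
computes it by the standard alternating fixed point: starting from all
reactions, repeatedly discard reactions whose reactants are not
producible from F through the survivors, and reactions with no
available catalyst, until stable.  Each prune only removes reactions
that no RAF inside the current survivor set could contain, so the fixed
point is the maxRAF; the suite cross-checks this against exhaustive
subset search on instances small enough to enumerate.

Around the maxRAF the package implements the standard structural
notions: **closed** RAFs (`is_closed_raf()`: the RAF already contains
every network reaction whose reactants and one catalyst it makes
available; the maxRAF is always closed, and a subRAF that is not closed
is *transient*), the **closure** of a subRAF (`closure_of_subraf()`,
iteratively adding supported reactions; idempotent by construction),
**co-RAFs** (`is_co_raf()`: reaction sets that are not RAFs alone but
form one jointly with a given RAF), **irrRAFs** (`find_irr_rafs()`:
RAFs containing no smaller RAF) and **union decomposability**
(`is_union_decomposable()`).

Two algorithmic choices deserve note:

* *irrRAF sampling* uses randomised single-reaction contraction: remove
  one reaction from the current RAF, recompute the maxRAF of the
  remainder, and descend while a non-empty RAF survives.  Every set
  this returns is a genuine irrRAF; sampling with many restarts may
  still miss some, which is why exhaustive mode (capped at 12 reactions,
  i.e. at most 4095 subsets — comfortably sub-second) exists alongside.
* *union decomposability* is decided through a coverage criterion
  rather than pair enumeration: a RAF is the union of two proper
  subRAFs exactly when each of its reactions lies in *some* proper
  subRAF.  (If such a cover exists, take a maximal proper subRAF A and,
  for any reaction outside A, a proper subRAF S containing it; A ∪ S is
  a RAF strictly above A, hence by maximality not proper, hence the
  whole set.)  Above the exhaustive cap the criterion is evaluated
  against sampled irrRAFs, which can yield a false negative but never a
  false positive.

## Determinism

All set iterations are ordered by locale-independent (radix)
lexicographic id, so every operation is bit-stable across runs and
platforms.  The two prunes inside the maxRAF sweep can be applied in
either order; the fixed point is the same, and the test suite asserts
this on random instances rather than taking it on faith.  Randomness
enters only through explicit integer seeds (irrRAF sampling, the
synthetic generators), and every report echoes its seed.

## The cultural-lineage semantics

`run_lineage()` applies ordered events to a population.  Each
individual i carries a foodset F_i and a disjoint foodset-derived set
¬F_i.  Social and individual learning add to F_i; creative events — the
catalysed reactions a (+ a′) →[b] c — add to ¬F_i.  Events only ever
add MRs: the model tracks the growth of conceptual networks, not
forgetting.  A creative product transmitted socially is *re-tagged* on
arrival: new information in the creator's mind is pre-existing
information for the recipient, so it lands in the recipient's foodset.
This asymmetry is the heart of the provenance model — it is what lets a
lineage cross from one mind to the next while keeping per-individual
books on where each idea came from.

Three design choices resolve points the formal description leaves open:

* **Catalysts are ordinary foodset MRs.**  The catalyst of the creative
  steps (domain knowledge together with the desire to express the
  inspirational source in the new medium, written n_i) is modelled as
  an MR the creator acquires through individual learning in step two.
  This makes the reflexive-autocatalysis condition checkable on the
  creator's CRS rather than leaving catalysis outside the formalism.
* **Background individuals.**  A social event may name a source the
  lineage has never seen (the music teacher, the long-dead carver).
  Such sources are auto-created holding the transmitted MRs as
  background foodset knowledge, flagged `background` in the ledger.
  Their own histories lie outside the modelled lineage; modelling them
  would regress without limit.  A source already present in the state
  must genuinely possess what it transmits, and an event violating this
  is an error — so the check is real wherever the lineage has the
  information to make it.
* **The final product's tag.**  The synthesis step's product is
  generated by creative thought and is therefore placed in the
  creator's ¬F_i (and its provenance recorded as creative), which is
  the reading consistent with the derived-set update and with the
  re-tagging rule at the audience step.

`lineage_to_crs()` projects one individual's history onto a CRS —
elements are their MRs, food is F_i, and each of their creative events
is a reaction — after which the whole RAF toolkit applies to minds.
`trace_origin()` walks any MR back through `derived_from` links to the
foodset items it ultimately rests on; because lineages are append-only,
these chains are finite and acyclic.

## The packaged case study

The package ships two literal fixture tables from a study of artworks
inspired by the Hohlenstein-Stadel Löwenmensch figurine: a participant
roster (nine artists, three of whom form the musical group SLT;
entities are therefore 7, with group members excluded from separate
counting) and a 3 × 4 presence/absence matrix of themes in the three
returned creative-process descriptions.  Theme counts are LH = 3,
D = 2, W = 2, S = 1; with the frequency rule "at least two
descriptions" plus the documented retention of S (kept because
subtractive sculpting was judged central despite appearing once), the
through-lines are LH, S, D, W.  The retention is an explicit parameter
(`retained`) rather than a hard-coded exception, so both the plain rule
and the study's rule are expressible.

`build_lineage_fixture()` emits the canonical six steps: socially
learned background knowledge, individual honing (producing the catalyst
n_i), social transmission of each through-line from the carver via the
study pamphlet, one cross-domain transfer reaction per through-line
(the formal description spells out the lion-human case and says the
other three are analogous; the fixture encodes them as three additional
reactions within step four so that the synthesis step's reactants all
exist), the catalysed synthesis of the finished piece, and transmission
to each audience member.  The group is modelled as a single actor, its
members metadata: the study data attribute one process description and
one creative product to the group as a unit.  Running the fixture
yields exactly five foodset-derived MRs for the musician (the four
transferred through-lines plus the piece), an empty derived set for the
listener, and a creator CRS whose maxRAF contains all five creative
reactions.

## The binary polymer generator

`generate_polymer_crs()` emulates the classic random chemistry in
which RAF emergence was first studied: elements are all strings up to
length n over a k-letter monomer alphabet (default binary), reactions
are all ligations x + y → xy within the length cap, food is all
strings up to length t, and each (element, reaction) catalysis pair is
included independently with probability p.  Defaults t = 2 and a
binary alphabet keep the foodset small relative to the universe, which
is what makes RAF emergence non-trivial; the phase-transition
experiments in the tests use n = 6 (126 elements, 516 ligations) with
50 replicates per grid point, sizes at which a full sweep runs in tens
of seconds while leaving the transition clearly visible between the
exact endpoints p = 0 (no catalysis, no RAF) and p = 1 (saturated
catalysis, all-reaction maxRAF).

One construction detail matters more than it looks: the uniform draw
deciding each catalysis pair depends only on the seed and the fixed
enumeration of elements and reactions — never on p.  A pair is included
when its draw is below p, so for a fixed seed the catalysis set at a
smaller p is a subset of the set at a larger p, and maxRAF size is
monotone in p *instance by instance*.  The monotonicity of the phase
curve is then an exact, assertable property rather than a statistical
one, and the replicate seeds (base seed + replicate index, reused
across the grid) preserve it through `estimate_raf_probability()`.
Cleavage reactions and template-based catalysis variants are
deliberately out of scope; ligation-only is the minimal repertoire
exhibiting the transition.

What the generator does *not* emulate: real chemical (or cognitive)
networks have highly non-uniform catalysis, correlated reaction
repertoires and dynamics on concentrations.  Passing tests on polymer
instances shows the algorithms are correct on the combinatorial
structure, not that any particular empirical system sits on a
particular side of the transition.  No numeric transition threshold is
asserted anywhere — only endpoint behaviour and monotonicity, which are
the properties the construction guarantees.

`random_crs()` is a second, structure-free generator (arbitrary small
reaction sets over generic elements, food a stated 30% fraction of
elements) used to fuzz the algorithms against an exhaustive
subset-enumeration oracle at sizes up to 12 reactions; the oracle suite
runs 200+ instances in well under a minute.

## Degenerate inputs and edge behaviour

The empty reaction subset is F-generated (vacuously) but is not a RAF:
RAFs are non-empty by definition, and this convention is applied
consistently (`is_raf(x, character())` is `FALSE`, the union property
is tested over non-empty subRAFs, an empty maxRAF is a distinct
"no RAF" status rather than an error).  A reaction with an empty
catalyst set is legal in a CRS — `crs_advisories()` flags it — but can
never join a RAF.  An element may appear as both reactant and catalyst
of the same reaction; nothing in the definitions forbids it, so it is
allowed and flagged as an advisory rather than rejected.  Parsing is
strict by default (every element declared) with an explicit
`implicit_elements` escape hatch, because silent auto-declaration turns
typos into phantom elements.

## Limitations

The lineage model is descriptive, not generative: it validates and
traces a given event sequence but does not sample event sequences, has
no forgetting, and assigns no magnitudes to catalytic "reactivity" (no
formula for reactivity exists to implement).  Stoichiometry and
concentrations are out of scope throughout — availability is set-based,
which is the right semantics for ideas and a simplification for
chemistry.  Exhaustive RAF enumeration is exponential and capped
accordingly; beyond the cap the sampling modes give one-sided
guarantees only.
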