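---
title: "Qualitative dynamics of SBGN Process Description maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative dynamics of SBGN Process Description maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbgndyn)
```

## Motivation

Molecular interaction maps in the SBGN Process Description (PD) language
describe reaction networks mechanistically: pools of molecules (possibly
decorated with post-translational state variables, possibly assembled into
complexes) are transformed by processes, and processes are modulated by other
pools through stimulation, inhibition, catalysis or necessary-stimulation
arcs.  Such maps are static knowledge.  `sbgndyn` turns them into qualitative
dynamical models and asks dynamical questions of the kind that matter for
coupled biological oscillators such as the circadian clock and the cell
cycle: can each phase of a cycle be reached, in order, repeatedly?  Which
initial states make that possible?  Which loss-of-function (LoF) or
gain-of-function (GoF) mutations block a checkpoint marker?

## The model

Every entity pool is abstracted to a binary automaton (0 = absent,
1 = present) and every process to a binary automaton (0 = switched off,
1 = switched on); the network is equivalent to a 1-safe Petri net.  The
translation implements a deliberately *permissive* Boolean interpretation —
the weakest firing condition compatible with the usual reading of
stimulations and inhibitions — so that no behaviour is excluded by an
arbitrary kinetic assumption:

* a process may switch **on** iff all its reactants are present, all
  necessary stimulations are active, all absolute inhibitions are inactive,
  and at least one plain stimulation is active *or* one plain inhibition is
  inactive;
* a process may switch **off** iff all its products are present;
* an entity may become **present** iff some process producing it is on;
* an entity may become **absent** iff some process consuming it is on and
  that process's products are all present.

A modulation whose source is a logical function is active iff the function
evaluates to true with present = true.  Updates are asynchronous — exactly
one automaton changes per step — so the dynamics are non-deterministic and
reachability means existence of *some* trajectory.

Three choices deserve justification because the firing rule alone does not
fix them:

* **Vacuous disjunct.** For a process with *no* plain stimulation, catalysis
  or inhibition arc, the "at least one stimulation active or one inhibition
  inactive" clause is taken to hold vacuously.  Otherwise unmodulated
  processes could never fire, which would contradict the evident intent of
  any map containing a plain synthesis or degradation reaction.  One
  consequence worth knowing: *adding* a stimulation arc to a previously
  unmodulated process makes the clause non-vacuous and can therefore remove
  behaviours; on processes that already carry a plain arc, added
  stimulations only ever add behaviours.
* **Catalysis and generic modulation count as stimulations** in the firing
  disjunction (catalysis is a subtype of stimulation in the PD type system;
  generic modulation carries no sign).  Both re-classings are logged per
  process at translation time (`attr(an, "arc_notes")`).
* **Absolute inhibition** exists in the data model but is never produced by
  parsing either supported file format; it can only be introduced explicitly
  (e.g. through an edit script).  Writing it to SBGN-ML degrades it to plain
  inhibition with a warning, because the format has no arc class for it.

Source/sink pools get no automaton; an empty reactant (product) set makes
the corresponding conjunct vacuous.  Stoichiometry is ignored — a Boolean
pool cannot count — so multiset participants collapse to sets.  Entity
automata whose direction has no enabling condition (an entity nothing
produces, for example) simply lack that transition rule.

## Structural identity and the marker grammar

All cross-map operations (merging, marker resolution, edit scripts) rely on
*structural equality* of entity pools: class, label, compartment, canonical
multiset of state variables, and recursively equal subunits.  Labels alone
would conflate, e.g., the free and the doubly phosphorylated forms of the
same protein.  State variables with a value but no site (as in `pRB(P|P)`)
are distinguished by an ordinal and canonically sorted by (value, site,
ordinal).

Markers are written in a compact textual grammar: `WEE1(P@Ser53)`,
`CCND1:CDK6(P@Thr):CDKN1B`.  Every `:` at nesting depth 0 is a subunit
separator.  That rule is ambiguous for subunit names that themselves contain
a colon (`SWI:SNF`), so `find_entity()` falls back, after exact structural
lookup fails, to comparing sorted depth-0 token multisets of the rendered
text against the map's inventory — the grouping and the subunit order no
longer matter, and the ambiguity is resolved by what the map actually
contains.  Parsing is case-sensitive and reports 0-based character offsets
on error.

## Reachability, phases, precursors, mutations

**Reachability** is exact explicit-state breadth-first search with a visited
set, so witnesses are minimal-length.  Exploration is capped by a state
budget (default 5e6) with `budget-exceeded` as a third verdict that is never
conflated with `unreachable`; downstream reports show it as "unknown".  A
seeded random-walk probe (`random_walk_reach()`) is available as an
explicitly non-exhaustive fallback for goals whose exact exploration is out
of budget; it can only ever confirm reachability.

**Phases.**  A cycle is an ordered list of phases, each with marker
entities; the model is in a phase when at least one of its markers is
present and all markers of all other phases *of the same cycle* are absent.
Scoping the "absent" set to the cycle (rather than to every marker of every
cycle in the analysis) keeps the two oscillators' validations independent,
coupling them only through the shared dynamics; the alternative reading
would make each phase goal depend on the other cycle's marker inventory.
Phase sequences (default four repeats) are checked by layered search:
frontier k+1 is the set of states satisfying goal k+1 reachable from
frontier k, and a state satisfying goal k may itself already satisfy goal
k+1.  For the packaged marker tables the marker sets of consecutive phases
are disjoint, so the adjacent-satisfaction convention is immaterial there.
Cycles with a single phase are accepted (useful for trivial marker probes)
even though the packaged cycle specifications all have at least two.

**Precursor states** answer "which minimal sets of initially present
entities allow every entity of the map to be produced?"  Producibility is
the least fixpoint that ignores modulations entirely: seeded entities are
producible, products of source processes are producible, and products of
processes whose reactants are all producible are producible.  Because
modulations are ignored, the fixpoint over-approximates true reachability,
so an entity outside it is certifiably unreachable — and, dually, a
precursor state never owes its verdicts to an accidentally impoverished
start.  Catalysts are modulations and hence invisible to the closure, which
is why enzymes with no producing process must sit in every precursor state.
Optimality is lexicographic in the configured order, by default: fewest
entities, then fewest state variables set to a value (counted recursively
through complex subunits — the counting unit had to be fixed somewhere, and
the recursive count is the one that does not depend on how deeply a subunit
is nested), then fewest complexes.  The search is exact: entities with no
producer are forced in, the remainder is enumerated by increasing
cardinality (or exhaustively when cardinality is not the first objective),
and every candidate is checked against the closure.  The required-entity
hook (`precursor_config(required = ...)`) generalizes the practice of
pinning a biologically privileged complex into every precursor state; only
inclusion is enforced, free forms are not excluded.

One deliberate deviation from a documented degenerate case: a map whose
only producer of an entity X consumes X is *feasible* here — X simply ends
up seeded in every solution, exactly as an unproduced enzyme does, because a
seeded entity is producible by definition.  Declaring such maps infeasible
would contradict that definition.

**Mutations.**  LoF removes an entity's 0→1 rules and forces it absent in
initial states; GoF removes its 1→0 rules and forces it present (the
mutated entity starts present — "forces its presence" has to bind at time
zero for the clamp to mean anything).  Guards referencing the entity are
untouched.  The blocking screen enumerates all subset-minimal mutation sets
up to a size bound over a candidate set and re-verifies each hit with a
fresh reachability query; within its declared bounds it is exhaustive,
which a desk-scale state space makes affordable where large-scale
deductive screens must accept non-exhaustiveness.  Trajectory reliance is
implemented as an existential surrogate — "some trajectory passes through
entity-present before (or at) goal satisfaction", decided by staged layered
search — rather than a disjunctive cut-set notion, which the per-entity
question does not require.

## Synthetic study systems

The package ships four hand-specified fixture maps, small enough that every
expected verdict is derivable both by hand and by brute force, plus a
seeded random generator used only for property-based testing:

* `make_toy_clock()` — a two-entity negative-feedback oscillator (A
  activates B's synthesis, B represses A's synthesis and stimulates A's
  degradation) with phases P1 = {A}, P2 = {B}.  It supports a four-repeat
  P1/P2 succession, and P2 becomes unreachable when P1 is disabled.
* `make_nad_motif()` — the metabolic circular dependency of the NAD+
  salvage pathway: marker production needs NAD, NAD comes from NMN via the
  ever-present NMNAT enzyme, NMN comes from NAM via NAMPT, and NAMPT
  production needs the marker.  Starting from NMN the circle is broken;
  starting from NAM nothing is reachable.  Its two precursor optima are
  {NAM, NMNAT} and {NMN, NMNAT}.
* `make_toy_coupled()` — the toy clock coupled to a linear three-step arm
  X1→X2→X3 whose last step needs a kinase W produced only under necessary
  stimulation by clock entity A.  The size-1 blocking screen for X3 over
  {A, B, W} finds exactly LoF(A), GoF(B), LoF(W); the GoF(B) hit is the
  cross-oscillator blockade pattern (a clock repressor locked on blocks the
  other cycle's checkpoint).
* `make_factor_motif()` — two compartment-shuttling entities with no de novo
  production and one three-metabolite cycle; its precursor optima factor
  combinatorially as 2 × 2 × 3 = 12, the desk-scale analogue of precursor
  multiplicity arising from translocation cycles and a metabolite cycle in a
  large merged map.

Fixtures use a single compartment ("cell", or two compartments where the
point *is* translocation) so marker resolution is unambiguous.  What the
fixtures do **not** emulate: realistic map sizes (hundreds of species),
transcription/translation layering, annotation-rich curation, or
CellDesigner layout conventions.  Tests passing on them establish the
correctness of the algorithms, not the biological adequacy of any
particular curated map.

## Numerical and procedural choices

* States are fixed-width 0/1 integer vectors in a canonical automaton order
  (entities by structural key, then processes by identifier); hashing uses
  the packed character form.  Translation is therefore deterministic: the
  same map always yields the identical network.
* BFS rather than DFS so that witnesses are minimal-length.
* The property suites compare the rule engine against a brute-force
  interpreter that re-derives the firing/update conditions directly from
  the map, exhaustively over all states of networks up to 12 automata
  (fixtures plus 100 seeded random maps of 3 entities and 3 processes,
  which keeps the exhaustive sweep at a few minutes on one CPU), and the
  precursor solver against exhaustive subset search on maps of up to ~7
  entities.
* The random generator draws maps deterministically per seed and restores
  the caller's RNG state, so test corpora are reproducible and generation
  never perturbs user code.

## Limitations

* Attractors, phase durations and any quantitative-time property are out of
  scope; the semantics sees only trajectory existence.
* The permissive interpretation over-approximates deliberately: a verdict
  of "reachable" means "not excluded by the map's logic", not "observed".
* CellDesigner support is read-only and covers the conceptual subset
  (species, included species, complexes, reactions, modifiers,
  compartments, annotations); full format fidelity is a non-goal.
* Exact search does not scale to maps with hundreds of species; the design
  trades scale for exhaustiveness and honest budget-exceeded verdicts.
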