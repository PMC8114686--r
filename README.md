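# sbgndyn

Qualitative dynamics of SBGN Process Description (PD) maps.

Curated molecular interaction maps — such as maps of the circadian clock or
the mammalian cell cycle drawn in CellDesigner or exchanged as SBGN-ML —
encode mechanisms, not behaviour. `sbgndyn` is for modellers who want to ask
dynamical questions of such maps without committing to kinetic parameters:
it manipulates and merges PD maps at the conceptual level, translates them
into asynchronous automata networks under a permissive Boolean semantics,
and analyses the result exactly.

## What it computes

Each entity pool and each process becomes a binary automaton. A process may
switch **on** iff all reactants are present, all necessary stimulations are
active, all absolute inhibitions are inactive, and at least one plain
stimulation is active or one inhibition is inactive; it may switch **off**
iff its products are all present. An entity may become present iff a
producing process is on, and absent iff a consuming process is on with all
its products present. One automaton changes per step (asynchronous update),
so reachability of a goal state means existence of a trajectory. On top of
this core the package provides:

* **Reachability / phase progression** — exact BFS with minimal-length
  witnesses and an explicit state budget (`budget-exceeded` is a verdict,
  never silently folded into "unreachable"); phase goals ("one marker of
  this phase present, all markers of the other phases absent"), repeated
  phase sequences via layered search, and marker *disabling* to test
  whether all routes to a phase pass through its predecessor.
* **Precursor states** — all lexicographically optimal sets of initially
  present entities from which every entity of the map is producible when
  modulations are ignored (fewest entities, then fewest set state
  variables, then fewest complexes).
* **Mutation screens** — all subset-minimal LoF/GoF mutation sets (up to a
  size bound, over a candidate set) that make a checkpoint marker
  unreachable, each independently re-verified; plus an existential
  trajectory-reliance test.
* **Map plumbing** — SBGN-ML 0.2/0.3 read/write, CellDesigner (extended
  SBML) import, serializable edit scripts for harmonization, structural
  merging, packaged phase-marker tables for the cell cycle and the
  circadian clock, and deterministic synthetic fixture maps.

## Worked example

Two coupled oscillators: a two-entity negative-feedback clock (A, B) whose
entity A gates, through a kinase W, the last step of a linear cycle arm
X1 → X2 → X3. Which single mutations on the clock side block the cycle's
checkpoint marker X3?

```r
library(sbgndyn)

map <- make_toy_coupled()
an  <- translate(map)
an
#> Automata network: 6 entity + 9 process automata; 29 transition rules

reachable(an, initial_state(an), goal_spec(present = "X3"), budget = 1e6)$verdict
#> [1] "reachable"

sets <- blocking_mutations(an, present = character(),
                           marker_goal = goal_spec(present = "X3"),
                           max_size = 1, candidates = c("A", "B", "W"),
                           budget = 1e6)
control_summary(list(X3 = sets), attr(map, "provenance"))
#>   marker entity kind source
#> 1     X3      A  LoF  clock
#> 2     X3      B  GoF  clock
#> 3     X3      W  LoF  cycle
```

Three size-1 sets block X3: losing the kinase W (cycle side), losing the
clock activator A, or — the interesting one — *forcing* the clock repressor
B, which locks A's synthesis off and starves the coupling. Phase
progression of the clock itself:

```r
validate_progression(an, map, list(character()), toy_clock_phases(),
                     repeats = 4, budget = 1e6)
#> Progression report for cycle 'toy-clock' (1 precursor state(s), 4 repeats)
#>
#> Precursor 1 :  
#> (A) markers reachable:  P1 1/1; P2 1/1 
#> (B) phases reachable:  P1 TRUE; P2 TRUE 
#> (C) with predecessor disabled:  P1(-P2)=TRUE; P2(-P1)=FALSE 
#> sequence x4: TRUE
```

Both phases are reachable, the four-repeat P1/P2 succession exists, and P2
is lost when P1 is disabled — every route to P2 passes through P1.

Minimal precursor states of the metabolic circular-dependency motif:

```r
compute_precursors(make_nad_motif())
#> [[1]]
#> [1] "NAM"   "NMNAT"
#>
#> [[2]]
#> [1] "NMN"   "NMNAT"
#>
#> attr(,"objective")
#>     min-cardinality min-state-variables       min-complexes
#>                   2                   0                   0
```

A command-line front end over the same functions (subcommands `fixtures`,
`merge`, `reach`, `precursor`, `validate`, `mutations`) is installed at
`inst/cli/sbgndyn.R`.

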