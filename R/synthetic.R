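## Hand-specified fixture maps.  These are deliberately small enough that
## every dynamical verdict used in the test suite can be re-derived both by
## hand and by brute-force enumeration.

mm <- function(label, compartment = "cell") entity_pool("macromolecule", label, compartment)
sc <- function(label, compartment = "cell") entity_pool("simple-chemical", label, compartment)

#' Two-entity negative-feedback oscillator map
#'
#' A miniature analogue of a transcriptional/translational negative feedback
#' loop: entity A is produced from a source process inhibited by B, B is
#' produced from a source process stimulated by A, A is degraded under
#' stimulation by B, and B is degraded unconditionally.  Phase P1 is marked by
#' A, phase P2 by B; the map supports a repeated P1/P2 phase succession under
#' the asynchronous qualitative semantics.
#'
#' @return a \code{pd_map} with entities \{A, B\} and processes
#'   \{tA, tB, dA, dB\}.
#' @export
make_toy_clock <- function() {
  A <- mm("A"); B <- mm("B")
  m <- pd_map("cell")
  m <- add_process(m, process_node("tA", products = list(A)))
  m <- add_process(m, process_node("tB", products = list(B)))
  m <- add_process(m, process_node("dA", reactants = list(A)))
  m <- add_process(m, process_node("dB", reactants = list(B)))
  m <- add_modulation(m, modulation("inhibition", B, "tA"))
  m <- add_modulation(m, modulation("stimulation", A, "tB"))
  m <- add_modulation(m, modulation("stimulation", B, "dA"))
  m
}

#' Phase table of the toy clock
#' @return a \code{cycle_spec} with phases P1 = \{A\} and P2 = \{B\}.
#' @export
toy_clock_phases <- function() {
  cycle_spec("toy-clock", list(
    phase("P1", list(marker("A", "cell"))),
    phase("P2", list(marker("B", "cell")))))
}

#' Metabolic circular-dependency motif (NAD+/NMN/NAM-like)
#'
#' Reproduces the salvage-pathway dependency structure in which a marker M
#' requires NAD, NAD is made from NMN by the ever-present NMNAT enzyme, but
#' NMN can only be made from NAM by NAMPT, whose own production requires M —
#' a circular necessary condition.  Starting material NMN breaks the circle;
#' starting material NAM does not.
#'
#' @return a \code{pd_map} with entities \{NAM, NMN, NAD, NMNAT, NAMPT, M\}.
#' @export
make_nad_motif <- function() {
  NAM <- sc("NAM"); NMN <- sc("NMN"); NAD <- sc("NAD")
  NMNAT <- mm("NMNAT"); NAMPT <- mm("NAMPT"); M <- mm("M")
  m <- pd_map("cell")
  m <- add_process(m, process_node("p1", reactants = list(NMN), products = list(NAD)))
  m <- add_process(m, process_node("p2", reactants = list(NAM), products = list(NMN)))
  m <- add_process(m, process_node("p3", products = list(M)))
  m <- add_process(m, process_node("p4", products = list(NAMPT)))
  m <- add_process(m, process_node("p5", reactants = list(NMN), products = list(NAM)))
  m <- add_modulation(m, modulation("catalysis", NMNAT, "p1"))
  m <- add_modulation(m, modulation("catalysis", NAMPT, "p2"))
  m <- add_modulation(m, modulation("necessary-stimulation", NAD, "p3"))
  m <- add_modulation(m, modulation("necessary-stimulation", M, "p4"))
  m
}

#' Coupled two-oscillator map
#'
#' Extends [make_toy_clock()] with a linear "cycle" arm X1 -> X2 -> X3 whose
#' last step needs the kinase W, itself produced only under necessary
#' stimulation by clock entity A — a miniature analogue of one oscillator
#' gating a checkpoint of the other.
#'
#' @return a \code{pd_map}.  The attribute \code{"provenance"} carries the
#'   entity partition (\code{"clock"} vs \code{"cycle"}) used by
#'   [control_summary()].
#' @export
make_toy_coupled <- function() {
  m <- make_toy_clock()
  X1 <- mm("X1"); X2 <- mm("X2"); X3 <- mm("X3"); W <- mm("W")
  m <- add_process(m, process_node("q1", products = list(X1)))
  m <- add_process(m, process_node("q2", reactants = list(X1), products = list(X2)))
  m <- add_process(m, process_node("q3", reactants = list(X2), products = list(X3)))
  m <- add_process(m, process_node("qW", products = list(W)))
  m <- add_process(m, process_node("q4", reactants = list(X3)))
  m <- add_modulation(m, modulation("necessary-stimulation", W, "q3"))
  m <- add_modulation(m, modulation("necessary-stimulation", mm("A"), "qW"))
  attr(m, "provenance") <- c(A = "clock", B = "clock",
                             X1 = "cycle", X2 = "cycle", X3 = "cycle",
                             W = "cycle")
  m
}

#' Phase table of the coupled map's linear cycle
#' @return a \code{cycle_spec} with phases C1 = \{X1\}, C2 = \{X2\},
#'   C3 = \{X3\}.
#' @export
toy_coupled_phases <- function() {
  cycle_spec("toy-cycle", list(
    phase("C1", list(marker("X1", "cell"))),
    phase("C2", list(marker("X2", "cell"))),
    phase("C3", list(marker("X3", "cell")))))
}

#' Precursor-factorization motif
#'
#' A map whose minimal precursor states factor combinatorially: two
#' independent translocation cycles (an entity shuttling between cytoplasm and
#' nucleoplasm, with no de novo production) each contribute a binary
#' localization choice, and a three-metabolite production/consumption cycle
#' (a -> b -> c -> a) contributes a ternary choice.  The optimal precursor
#' states are exactly the 2 x 2 x 3 = 12 combinations.
#'
#' @return a \code{pd_map}.
#' @export
make_factor_motif <- function() {
  m <- pd_map(c("cytoplasm", "nucleoplasm"))
  for (lab in c("T", "E")) {
    cy <- mm(lab, "cytoplasm"); nu <- mm(lab, "nucleoplasm")
    m <- add_process(m, process_node(paste0(lab, "_in"),
                                     reactants = list(cy), products = list(nu)))
    m <- add_process(m, process_node(paste0(lab, "_out"),
                                     reactants = list(nu), products = list(cy)))
  }
  a <- sc("a", "cytoplasm"); b <- sc("b", "cytoplasm"); cc <- sc("c", "cytoplasm")
  m <- add_process(m, process_node("r_ab", reactants = list(a), products = list(b)))
  m <- add_process(m, process_node("r_bc", reactants = list(b), products = list(cc)))
  m <- add_process(m, process_node("r_ca", reactants = list(cc), products = list(a)))
  m
}

## ---- seeded random PD maps --------------------------------------------------

#' Parameters for the random PD-map generator
#'
#' @param n_entities,n_processes non-negative counts.
#' @param modulation_density mean number of modulation arcs per process.
#' @param frac_necessary,frac_inhibition fractions of modulation arcs drawn as
#'   necessary stimulations / inhibitions (remainder are stimulations).
#' @param seed integer seed; the same parameters and seed always yield an
#'   identical map.
#' @return a list of class \code{generator_params}.
#' @export
generator_params <- function(n_entities, n_processes, modulation_density = 1,
                             frac_necessary = 0.2, frac_inhibition = 0.3,
                             seed = 1L) {
  stopifnot(n_entities >= 0, n_processes >= 0, modulation_density >= 0,
            frac_necessary >= 0, frac_inhibition >= 0,
            frac_necessary + frac_inhibition <= 1)
  if (n_processes > 0 && n_entities == 0)
    stop("cannot generate processes with no entities")
  structure(list(n_entities = as.integer(n_entities),
                 n_processes = as.integer(n_processes),
                 modulation_density = modulation_density,
                 frac_necessary = frac_necessary,
                 frac_inhibition = frac_inhibition,
                 seed = as.integer(seed)),
            class = "generator_params")
}

with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random PD map
#'
#' Draws a connected map (every entity participates in at least one process)
#' with the requested entity and process counts; at least one process is a
#' source so that the producibility closure is non-trivial.  Modulation arcs
#' are drawn per process with the configured density and class mix.
#' Deterministic for a given parameter set.
#'
#' @param params a [generator_params()] object.
#' @return a \code{pd_map}.
#' @export
random_map <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  with_local_seed(params$seed, {
    ents <- lapply(seq_len(params$n_entities), function(i) mm(paste0("E", i)))
    m <- pd_map("cell")
    for (e in ents) m <- add_entity(m, e)
    if (params$n_processes == 0L) return(m)
    touched <- rep(FALSE, params$n_entities)
    for (j in seq_len(params$n_processes)) {
      pid <- paste0("p", j)
      if (j == 1L) {
        # guaranteed source process
        prod_idx <- sample.int(params$n_entities, 1L)
        react_idx <- integer()
      } else {
        # prefer entities not yet attached to any process
        free <- which(!touched)
        prod_idx <- if (length(free)) free[sample.int(length(free), 1L)]
                    else sample.int(params$n_entities, 1L)
        react_pool <- setdiff(seq_len(params$n_entities), prod_idx)
        nreact <- sample(0:min(2L, length(react_pool)), 1L)
        react_idx <- if (nreact) sample(react_pool, nreact) else integer()
      }
      touched[c(prod_idx, react_idx)] <- TRUE
      m <- add_process(m, process_node(pid,
                                       reactants = ents[react_idx],
                                       products = ents[prod_idx]))
      nmod <- stats::rpois(1L, params$modulation_density)
      if (nmod > 0L) {
        srcs <- sample.int(params$n_entities, min(nmod, params$n_entities))
        for (s in srcs) {
          u <- stats::runif(1)
          cls <- if (u < params$frac_necessary) "necessary-stimulation"
                 else if (u < params$frac_necessary + params$frac_inhibition) "inhibition"
                 else "stimulation"
          m <- add_modulation(m, modulation(cls, ents[[s]], pid))
        }
      }
    }
    # attach any still-isolated entity via a degradation process
    for (i in which(!touched))
      m <- add_process(m, process_node(paste0("deg_E", i), reactants = ents[i]))
    m
  })
}
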