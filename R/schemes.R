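#' Specify a set of DNA sequence mutations
#'
#' Describes a native sequence and a set of equal-length mutant sequences
#' over \{A, C, G, T\}, plus the perturbation scheme used to realise them
#' alchemically: one lambda per base pair (`"one_lambda_per_pair"`), one
#' lambda per base on each strand (`"two_lambda"`), or the latter plus a
#' quadratic inter-site coupling bias between the paired lambdas
#' (`"coupled_two_lambda"`).
#'
#' For the coupled scheme, `coupling_strength` fills the \eqn{\Psi} tensor
#' on matched (complementary) non-reference substituent pairs.  The default
#' is -2 kcal/mol: a *decoupling* quadratic that penalises joint activation
#' of the paired mutant lambdas.  After flattening relinearises the
#' landscape, this lowers the mispaired intermediates relative to the
#' matched endstates, which is what lets the base pair transit stepwise
#' (one strand at a time) and spreads transitions over mismatched states.
#' A positive value would instead stabilise concerted matched-pair moves.
#'
#' @param native native sequence string.
#' @param mutants character vector of mutant sequences, same length as
#'   `native`, at least one position differing.
#' @param scheme one of `"one_lambda_per_pair"`, `"two_lambda"`,
#'   `"coupled_two_lambda"` (abbreviations `"1l"`, `"2l"`, `"coupled2l"`
#'   are accepted).
#' @param coupling_strength Psi fill value, kcal/mol (coupled scheme only).
#' @return An object of class `mutation_spec`.
#' @export
#' @examples
#' mutation_spec("GGTCAA", "GATAAA", "one_lambda_per_pair")
mutation_spec <- function(native, mutants,
                          scheme = c("one_lambda_per_pair", "two_lambda",
                                     "coupled_two_lambda"),
                          coupling_strength = -2) {
  scheme <- normalize_scheme(scheme)
  native <- toupper(native)
  mutants <- toupper(mutants)
  ok <- function(x) grepl("^[ACGT]+$", x)
  if (!ok(native) || !all(ok(mutants)))
    stop_msldyn("sequences must be over the alphabet {A, C, G, T}")
  if (any(nchar(mutants) != nchar(native)))
    stop_msldyn("all mutant sequences must match the native length")
  if (all(mutants == native))
    stop_msldyn("at least one position must differ from the native sequence")
  structure(list(native = native, mutants = mutants, scheme = scheme,
                 coupling_strength = coupling_strength),
            class = "mutation_spec")
}

normalize_scheme <- function(scheme) {
  scheme <- scheme[1L]
  alias <- c("1l" = "one_lambda_per_pair", "2l" = "two_lambda",
             "coupled2l" = "coupled_two_lambda")
  if (scheme %in% names(alias)) scheme <- alias[[scheme]]
  match.arg(scheme, c("one_lambda_per_pair", "two_lambda",
                      "coupled_two_lambda"))
}

#' Build the alchemical topology realising a perturbation scheme
#'
#' Variant positions (where any mutant differs from the native) become
#' alchemical sites; non-variant positions are untouched.  Under
#' `one_lambda_per_pair` each variant position is a single site whose
#' substituents are Watson-Crick base pairs labelled by the primary-strand
#' base (the complement is implied).  Under the two-lambda schemes each
#' variant position contributes two paired sites, one per strand, whose
#' substituents are individual bases; vertex combinations with
#' non-complementary partners are mispaired and labelled
#' `"primary/complement-reading"`.  The coupled scheme additionally attaches
#' a `Psi` coupling matrix (see [mutation_spec()]) with
#' \eqn{\Psi_{s1,tj} = \Psi_{si,t1} = 0} on reference substituents.
#'
#' The native substituent is always first at each site, so the native
#' sequence is the reference endstate.
#'
#' @param spec a [mutation_spec()].
#' @return An [alch_topology()]; for the coupled scheme it carries a `Psi`
#'   matrix field consumed by [alf_flatten()] / [bias_parameters()].
#' @export
#' @examples
#' top <- build_scheme(mutation_spec("GGTCAA", "GATAAA"))
#' sort(top$vertices$label)   # the four endstate sequences
build_scheme <- function(spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  nat <- strsplit(spec$native, "")[[1]]
  muts <- strsplit(spec$mutants, "")
  L <- length(nat)
  variant <- sort(unique(unlist(lapply(muts, function(m) which(m != nat)))))
  # native-first substituent sets per variant position
  subs <- lapply(variant, function(p) {
    alt <- unique(c(nat[p], vapply(muts, `[`, character(1), p)))
    alt
  })

  if (spec$scheme == "one_lambda_per_pair") {
    sites <- setNames(subs, paste0("bp", variant))
    top <- alch_topology(sites, strand = rep("pair", length(sites)),
                         position = variant, native = spec$native)
    return(top)
  }

  # two-lambda schemes: primary + complement site per variant position
  sites <- list(); strand <- character(0); position <- integer(0)
  pairing <- list()
  for (k in seq_along(variant)) {
    p <- variant[k]
    sites[[paste0("pos", p, ".fwd")]] <- subs[[k]]
    sites[[paste0("pos", p, ".rev")]] <- wc_complement(subs[[k]])
    strand <- c(strand, "primary", "complement")
    position <- c(position, p, p)
    pairing[[k]] <- c(2L * k - 1L, 2L * k)
  }
  top <- alch_topology(sites, pairing = pairing, strand = strand,
                       position = position, native = spec$native)
  if (spec$scheme == "coupled_two_lambda") {
    Psi <- matrix(0, top$P, top$P)
    for (k in seq_along(variant)) {
      s <- 2L * k - 1L; t <- 2L * k
      n <- top$n_sub[s]
      for (i in 2:n) {  # skip reference substituent (index 1)
        pi <- flat_index(top, s, i)
        qi <- flat_index(top, t, i)  # complement subs are stored in the same order
        Psi[pi, qi] <- Psi[qi, pi] <- spec$coupling_strength
      }
    }
    top$Psi <- Psi
  }
  top
}

#' Properly paired vertex states of a topology
#'
#' Returns the vertex combinations in which every Watson-Crick paired site
#' pair carries complementary bases.  For one-lambda topologies (no paired
#' sites) every vertex is matched.
#'
#' @param topology an [alch_topology()].
#' @return A data frame (subset of `topology$vertices`).
#' @export
matched_state_filter <- function(topology) {
  stopifnot(inherits(topology, "alch_topology"))
  topology$vertices[topology$vertices$matched, , drop = FALSE]
}
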