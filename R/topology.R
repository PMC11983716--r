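#' Alchemical topology: sites, substituents and base pairing
#'
#' An alchemical topology defines the coordinate space of a multisite
#' lambda-dynamics run: an ordered list of sites, each carrying at least two
#' substituents, plus an optional pairing map that links two sites as a
#' Watson-Crick pair (used by the two-lambda perturbation schemes).  Every
#' combination of one substituent per site (a "vertex" of the lambda
#' hypercube) corresponds to a physical or mispaired sequence; the full
#' vertex enumeration with sequence labels is stored in the object.
#'
#' @param sites named list; one element per site, each a character vector of
#'   substituent labels (length >= 2).  Names are the site labels and must be
#'   unique.
#' @param pairing optional two-column integer matrix (or list of length-2
#'   vectors) of site index pairs to be treated as Watson-Crick partners.
#'   Each site may appear in at most one pair.
#' @param strand optional character vector, one of `"pair"`, `"primary"`,
#'   `"complement"` per site.  Scheme builders use it to mark which strand a
#'   site lives on; defaults to `"pair"` (strand-agnostic).
#' @param position optional integer vector of sequence positions per site
#'   (used by [build_scheme()] to embed vertex labels in a full sequence).
#' @param native optional native sequence string used for labelling.
#'
#' @return An object of class `alch_topology` with fields `site_labels`,
#'   `n_sub`, `sub_labels`, `pairing` (integer partner index or `NA`),
#'   `offset` (0-based start of each site's block in the flattened
#'   lambda/theta vector), `P` (total number of (site, substituent)
#'   coordinates), and `vertices` (a data frame enumerating all vertex
#'   combinations with `label` and `matched` columns).
#' @seealso [build_scheme()], [matched_state_filter()]
#' @export
#' @examples
#' top <- alch_topology(list(pos4 = c("C", "A")))
#' top$vertices
alch_topology <- function(sites, pairing = NULL, strand = NULL,
                          position = NULL, native = NULL) {
  if (!is.list(sites) || length(sites) < 1L)
    stop_msldyn("'sites' must be a non-empty named list of substituent labels")
  labels <- names(sites)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels)))
    stop_msldyn("site labels must be unique and non-empty")
  n_sub <- vapply(sites, length, integer(1))
  if (any(n_sub < 2L))
    stop_msldyn("every site needs at least 2 substituents (N_s >= 2)")
  M <- length(sites)

  pair_vec <- rep(NA_integer_, M)
  if (!is.null(pairing)) {
    if (is.list(pairing)) pairing <- do.call(rbind, pairing)
    pairing <- matrix(as.integer(pairing), ncol = 2L)
    for (r in seq_len(nrow(pairing))) {
      a <- pairing[r, 1L]; b <- pairing[r, 2L]
      if (a == b || a < 1L || b > M || b < 1L || a > M)
        stop_msldyn("invalid pairing entry (", a, ", ", b, ")")
      if (!is.na(pair_vec[a]) || !is.na(pair_vec[b]))
        stop_msldyn("a site can be paired with at most one other site")
      pair_vec[a] <- b; pair_vec[b] <- a
    }
  }
  strand <- strand %||% rep("pair", M)
  stopifnot(length(strand) == M, all(strand %in% c("pair", "primary", "complement")))

  offset <- c(0L, cumsum(n_sub))[seq_len(M)]
  top <- structure(
    list(site_labels = labels, n_sub = n_sub, sub_labels = unname(sites),
         pairing = pair_vec, strand = strand,
         position = position, native = native,
         offset = offset, P = sum(n_sub)),
    class = "alch_topology")
  top$vertices <- enumerate_vertices(top)
  top
}

# Watson-Crick complement (vectorised over single characters)
wc_complement <- function(b) {
  map <- c(A = "T", T = "A", G = "C", C = "G")
  out <- map[b]
  if (anyNA(out)) stop_msldyn("invalid base(s): ", paste(b[is.na(out)], collapse = ", "))
  unname(out)
}

# Enumerate every vertex (one substituent per site), label it and flag
# whether all paired sites carry Watson-Crick complementary bases.
enumerate_vertices <- function(top) {
  M <- length(top$n_sub)
  if (prod(top$n_sub) > 1e4)
    stop_msldyn("vertex enumeration too large (> 10000 combinations)")
  grid <- do.call(expand.grid, c(lapply(top$n_sub, seq_len), KEEP.OUT.ATTRS = FALSE))
  names(grid) <- paste0("s", seq_len(M))
  matched <- rep(TRUE, nrow(grid))
  for (s in seq_len(M)) {
    t <- top$pairing[s]
    if (!is.na(t) && s < t) {
      bs <- top$sub_labels[[s]][grid[[s]]]
      bt <- top$sub_labels[[t]][grid[[t]]]
      matched <- matched & (wc_complement(bs) == bt)
    }
  }
  grid$label <- vertex_labels(top, grid, matched)
  grid$matched <- matched
  grid
}

# Sequence labels: embed substituent choices into the native sequence when
# positions are known; mispaired vertices are labelled
# "primary/complement-strand-reading".
vertex_labels <- function(top, grid, matched) {
  M <- length(top$n_sub)
  prim <- which(top$strand != "complement")
  n <- nrow(grid)
  if (is.null(top$native) || is.null(top$position)) {
    return(vapply(seq_len(n), function(r)
      paste(vapply(seq_len(M), function(s) top$sub_labels[[s]][grid[r, s]],
                   character(1)), collapse = ""), character(1)))
  }
  base_seq <- strsplit(top$native, "")[[1]]
  lab <- character(n)
  for (r in seq_len(n)) {
    sq <- base_seq
    for (s in prim) sq[top$position[s]] <- top$sub_labels[[s]][grid[r, s]]
    lab[r] <- paste(sq, collapse = "")
    if (!matched[r]) {
      # what the complementary strand encodes, read on the primary strand
      sq2 <- base_seq
      for (s in which(top$strand == "complement"))
        sq2[top$position[s]] <- wc_complement(top$sub_labels[[s]][grid[r, s]])
      for (s in prim[top$strand[prim] == "pair"])
        sq2[top$position[s]] <- top$sub_labels[[s]][grid[r, s]]
      lab[r] <- paste0(lab[r], "/", paste(sq2, collapse = ""))
    }
  }
  lab
}

#' @export
print.alch_topology <- function(x, ...) {
  cat("Alchemical topology:", length(x$n_sub), "site(s),",
      x$P, "lambda coordinates\n")
  for (s in seq_along(x$n_sub)) {
    cat(sprintf("  %s [%s]: %s%s\n", x$site_labels[s], x$strand[s],
                paste(x$sub_labels[[s]], collapse = "/"),
                if (!is.na(x$pairing[s]))
                  paste0("  (paired with ", x$site_labels[x$pairing[s]], ")")
                else ""))
  }
  cat(sum(x$vertices$matched), "matched /", nrow(x$vertices), "total endstates\n")
  invisible(x)
}

# flat index of (site s, substituent i)
flat_index <- function(top, s, i) top$offset[s] + i

# lambda vector of a vertex (row index into top$vertices)
vertex_lambda <- function(top, v) {
  lam <- numeric(top$P)
  for (s in seq_along(top$n_sub))
    lam[flat_index(top, s, top$vertices[v, s])] <- 1
  lam
}

# coordinate names "site:substituent" in site-major order
coord_names <- function(top) {
  unlist(lapply(seq_along(top$n_sub), function(s)
    paste0(top$site_labels[s], ":", top$sub_labels[[s]])))
}

check_lambda <- function(lam, top, tol = 1e-8) {
  if (length(lam) != top$P)
    stop_msldyn("lambda has length ", length(lam), ", expected ", top$P)
  if (any(!is.finite(lam))) stop_msldyn("non-finite lambda")
  for (s in seq_along(top$n_sub)) {
    idx <- top$offset[s] + seq_len(top$n_sub[s])
    if (abs(sum(lam[idx]) - 1) > tol || any(lam[idx] < -tol) || any(lam[idx] > 1 + tol))
      stop_msldyn("lambda violates the simplex constraint at site ", s)
  }
  invisible(TRUE)
}
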