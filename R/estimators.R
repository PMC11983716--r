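#' Assign trajectory frames to endstate bins
#'
#' A frame belongs to a sequence when, at every site, the substituent that
#' sequence prescribes has \eqn{\lambda \ge \lambda_c}; otherwise it is
#' unassigned.  The cutoff convention \eqn{\lambda_c = 0.99} makes the
#' population estimator essentially exact.
#'
#' @param traj a `lambda_trajectory`.
#' @param lambda_c cutoff in (0.5, 1).
#' @return An object of class `endstate_series`: `label` (character per
#'   frame, `NA` when unassigned), `step`, `frame_time` (model time per
#'   frame), `lambda_c`, `topology`.
#' @export
assign_endstates <- function(traj, lambda_c = 0.99) {
  stopifnot(inherits(traj, "lambda_trajectory"),
            lambda_c > 0.5, lambda_c < 1)
  top <- traj$topology
  M <- length(top$n_sub)
  n <- nrow(traj$lambda)
  # per site: which substituent exceeds the cutoff (at most one, lambda_c > 0.5)
  sel <- matrix(NA_integer_, n, M)
  for (s in seq_len(M)) {
    idx <- top$offset[s] + seq_len(top$n_sub[s])
    block <- traj$lambda[, idx, drop = FALSE]
    w <- max.col(block, ties.method = "first")
    hit <- block[cbind(seq_len(n), w)] >= lambda_c
    sel[hit, s] <- w[hit]
  }
  assigned <- !apply(sel, 1L, anyNA)
  lab <- rep(NA_character_, n)
  if (any(assigned)) {
    key_v <- do.call(paste, c(as.data.frame(top$vertices[, seq_len(M), drop = FALSE]),
                              sep = "_"))
    key_f <- do.call(paste, c(as.data.frame(sel[assigned, , drop = FALSE]), sep = "_"))
    lab[assigned] <- top$vertices$label[match(key_f, key_v)]
  }
  structure(list(label = lab, step = traj$step,
                 frame_time = traj$settings$save_interval * traj$settings$timestep,
                 lambda_c = lambda_c, topology = top),
            class = "endstate_series")
}

#' @export
print.endstate_series <- function(x, ...) {
  n <- length(x$label)
  cat("Endstate series:", n, "frames,",
      sum(!is.na(x$label)), "assigned (lambda_c =", x$lambda_c, ")\n")
  tb <- table(x$label)
  if (length(tb)) print(tb)
  invisible(x)
}

#' Count transitions between endstates
#'
#' Unassigned gaps are transparent: the series is collapsed to the sequence
#' of assigned visits, and a transition *to* sequence `m` is counted each
#' time `m` is entered from a different previously visited sequence.  The
#' first visit is not a transition.  Rates are counts per unit model time.
#'
#' @param series an [assign_endstates()] result, or a list of them
#'   (replicas; counted independently and summed).
#' @return List with `counts` (named integer vector over all endstate
#'   labels of the topology), `total`, `rates` (counts / model time),
#'   `model_time`, and `visits` (the collapsed visit sequences).
#' @export
count_transitions <- function(series) {
  if (inherits(series, "endstate_series")) series <- list(series)
  stopifnot(length(series) >= 1)
  top <- series[[1]]$topology
  labels <- top$vertices$label
  counts <- setNames(integer(length(labels)), labels)
  visits_all <- list()
  total_time <- 0
  for (se in series) {
    total_time <- total_time + length(se$label) * se$frame_time
    v <- se$label[!is.na(se$label)]
    if (!length(v)) { visits_all[[length(visits_all) + 1L]] <- character(0); next }
    v <- rle(v)$values
    visits_all[[length(visits_all) + 1L]] <- v
    if (length(v) > 1L)
      for (k in 2:length(v)) counts[v[k]] <- counts[v[k]] + 1L
  }
  list(counts = counts, total = sum(counts),
       rates = counts / total_time, model_time = total_time,
       visits = visits_all)
}

#' Population-based free energies of the endstates
#'
#' Implements the lambda-dynamics population estimator: with \eqn{P_m} the
#' fraction of assigned frames binned to sequence \eqn{m},
#' \deqn{\Delta G_m = -k_BT \ln(P_m / P_{ref}) - (B_m - B_{ref}),}
#' where \eqn{B_m} is the applied bias energy evaluated at vertex \eqn{m}
#' (the linear and inter-site coupling terms survive at a vertex; the
#' intra-site quadratic vanishes).  The explicit bias correction removes
#' the applied flattening bias rather than assuming a perfectly flattened
#' landscape; disable it with `bias_correction = FALSE` to mimic that
#' assumption.  Standard errors come from a block bootstrap over trajectory
#' blocks (block length = frames / 20, at least 1).  Sequences never
#' observed are flagged unavailable (`NA`), never infinite.
#'
#' @param series an [assign_endstates()] result or list of them (replicas).
#' @param bias the [bias_parameters()] the trajectories were generated
#'   under.
#' @param temperature kelvin.
#' @param n_boot bootstrap resamples.
#' @param seed optional bootstrap seed.
#' @param reference reference sequence label; default the native (first
#'   matched) endstate.  Must be observed at least once.
#' @param bias_correction subtract the applied vertex bias (default TRUE).
#' @return Object of class `fe_estimate`: a data frame with columns
#'   `sequence`, `dG`, `se`, `n_frames`, `available`, plus attributes
#'   `reference`, `temperature`, `lambda_c`, `bias_correction`,
#'   `transitions`.
#' @export
free_energy_from_populations <- function(series, bias, temperature = 298,
                                         n_boot = 50L, seed = NULL,
                                         reference = NULL,
                                         bias_correction = TRUE) {
  if (inherits(series, "endstate_series")) series <- list(series)
  stopifnot(length(series) >= 1, inherits(bias, "bias_parameters"))
  if (!is.null(seed)) set.seed(seed)
  top <- bias$topology
  matched <- matched_state_filter(top)
  seqs <- matched$label
  reference <- reference %||% seqs[1L]
  if (!reference %in% seqs) stop_msldyn("unknown reference sequence ", reference)
  kT <- .kB * temperature

  Bv <- if (bias_correction) vertex_bias_energy(bias) else numeric(nrow(top$vertices))
  B <- setNames(Bv[match(seqs, top$vertices$label)], seqs)

  count_labels <- function(lab_list) {
    cnt <- setNames(numeric(length(seqs)), seqs)
    for (lab in lab_list) {
      tb <- table(factor(lab[!is.na(lab)], levels = seqs))
      cnt <- cnt + as.numeric(tb)
    }
    cnt
  }
  dg_from <- function(cnt) {
    dg <- -kT * log(cnt / cnt[reference]) - (B - B[reference])
    dg[cnt == 0] <- NA_real_
    dg
  }

  labs <- lapply(series, `[[`, "label")
  cnt <- count_labels(labs)
  if (cnt[reference] == 0)
    stop_msldyn("reference sequence ", reference, " was never observed")
  dG <- dg_from(cnt)

  boot <- matrix(NA_real_, n_boot, length(seqs))
  for (k in seq_len(n_boot)) {
    res <- lapply(labs, function(lab) {
      n <- length(lab)
      bl <- max(1L, n %/% 20L)
      starts <- seq(1L, n, by = bl)
      pick <- sample(starts, length(starts), replace = TRUE)
      lab[unlist(lapply(pick, function(s) s:min(s + bl - 1L, n)))]
    })
    cb <- count_labels(res)
    if (cb[reference] > 0) boot[k, ] <- dg_from(cb)
  }
  se <- apply(boot, 2L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1L) sd(v) else NA_real_
  })
  se[is.na(dG)] <- NA_real_
  se[seqs == reference] <- 0

  tr <- count_transitions(series)
  out <- data.frame(sequence = seqs, dG = unname(dG), se = unname(se),
                    n_frames = unname(cnt),
                    available = unname(cnt > 0), stringsAsFactors = FALSE)
  structure(out, class = c("fe_estimate", "data.frame"),
            reference = reference, temperature = temperature,
            lambda_c = series[[1]]$lambda_c,
            bias_correction = bias_correction,
            transitions = tr)
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat("Endstate free energies relative to", attr(x, "reference"),
      "(kcal/mol, lambda_c =", attr(x, "lambda_c"), ")\n")
  y <- as.data.frame(x)
  y$dG <- ifelse(y$available, sprintf("%.3f", y$dG), "--")
  y$se <- ifelse(y$available, sprintf("%.3f", y$se), "--")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Thermodynamic-cycle assembly of relative binding free energies
#'
#' The binding free-energy change of a mutation is the difference of its
#' alchemical mutation free energies in the bound and unbound ensembles:
#' \eqn{\Delta\Delta G_b = \Delta G_{bound} - \Delta G_{unbound}}, with the
#' standard error combined in quadrature.  Legs flagged unavailable
#' propagate unavailability (never infinities).
#'
#' @param bound,unbound [free_energy_from_populations()] results over the
#'   same sequence set and reference.
#' @return Object of class `ddg_result`: data frame with `sequence`, `ddG`,
#'   `se`, `available`; attribute `legs` keeps both inputs.
#' @export
ddg_cycle <- function(bound, unbound) {
  stopifnot(inherits(bound, "fe_estimate"), inherits(unbound, "fe_estimate"))
  if (!identical(bound$sequence, unbound$sequence))
    stop_msldyn("bound and unbound legs cover different sequence sets")
  if (!identical(attr(bound, "reference"), attr(unbound, "reference")))
    stop_msldyn("bound and unbound legs use different reference sequences")
  ddG <- bound$dG - unbound$dG
  se <- sqrt(bound$se^2 + unbound$se^2)
  avail <- bound$available & unbound$available
  ddG[!avail] <- NA_real_; se[!avail] <- NA_real_
  structure(data.frame(sequence = bound$sequence, ddG = ddG, se = se,
                       available = avail, stringsAsFactors = FALSE),
            class = c("ddg_result", "data.frame"),
            reference = attr(bound, "reference"),
            legs = list(bound = bound, unbound = unbound))
}

#' @export
print.ddg_result <- function(x, ...) {
  cat("Relative binding free energies (kcal/mol) vs", attr(x, "reference"), "\n")
  y <- as.data.frame(x)
  y$ddG <- ifelse(y$available, sprintf("%.3f", y$ddG), "--")
  y$se <- ifelse(y$available, sprintf("%.3f", y$se), "--")
  print(y[, c("sequence", "ddG", "se")], row.names = FALSE)
  invisible(x)
}

#' Ranked multi-mutant report
#'
#' Tabulates every physical sequence reachable in the topology (including
#' the single-position intermediates automatically present in multi-site
#' runs) with its relative binding free energy, standard error, frame
#' counts and transition counts, sorted by increasing \eqn{\Delta\Delta G}.
#'
#' @param result a [ddg_cycle()] result.
#' @param topology the [alch_topology()] the runs used.
#' @return A data frame, one row per matched sequence.
#' @export
multi_mutant_report <- function(result, topology) {
  stopifnot(inherits(result, "ddg_result"), inherits(topology, "alch_topology"))
  legs <- attr(result, "legs")
  trb <- attr(legs$bound, "transitions")$counts
  tru <- attr(legs$unbound, "transitions")$counts
  out <- data.frame(
    sequence = result$sequence, ddG = result$ddG, se = result$se,
    available = result$available,
    n_bound = legs$bound$n_frames, n_unbound = legs$unbound$n_frames,
    transitions_bound = as.integer(trb[result$sequence]),
    transitions_unbound = as.integer(tru[result$sequence]),
    stringsAsFactors = FALSE)
  out[order(out$ddG, na.last = TRUE), , drop = FALSE]
}
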