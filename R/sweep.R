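# ---- fast replicate core ----------------------------------------------------

.normalize_masks <- function(masks, full) {
  if (!length(masks)) return(integer(0))
  anchor <- bitwAnd(full, -full)
  flip <- bitwAnd(masks, anchor) != 0L
  masks[flip] <- bitwAnd(full, bitwNot(masks[flip]))
  sort(unique(masks))
}

# one simulated replicate at HGT fraction h; returns per-method correctness
# and F-sister-B flags. All randomness comes from the current RNG state.
.run_replicate <- function(config, h, methods) {
  G <- config$genes; L <- config$len
  seqm <- .evolve_int(config$species_tree, G * L, config$model)
  k <- round(G * h)
  if (k > 0L) {
    fams <- sort(sample.int(G, k))
    for (i in fams) {
      cols <- ((i - 1L) * L + 1L):(i * L)
      seqm[config$recipient, cols] <- seqm[config$donor, cols]
    }
  }
  seqm <- seqm[setdiff(rownames(seqm), config$donor), , drop = FALSE]
  ref <- sort(rownames(seqm))
  seqm <- seqm[ref, , drop = FALSE]
  full <- .mask_of(ref, ref)
  true_tree <- restrict_to_taxa(config$species_tree, ref)
  true_masks <- .normalize_masks(.split_masks(true_tree, ref), full)
  cherry_mask <- if (all(c("B", config$recipient) %in% ref)) {
    .normalize_masks(.mask_of(c("B", config$recipient), ref), full)
  } else NA_integer_

  out <- list()
  pd <- NULL
  for (m in methods) {
    if (m == "supermatrix-NJ") {
      pair <- combn(length(ref), 2L)
      p <- vapply(seq_len(ncol(pair)), function(kk)
        mean(seqm[pair[1, kk], ] != seqm[pair[2, kk], ]), numeric(1))
      d <- .square_from_pairs(kimura_correct(p), pair, ref)
      nj <- .nj_core(d, ref, ref = ref)
      masks <- .normalize_masks(nj$masks, full)
    } else if (m == "quartet-supertree") {
      if (is.null(pd)) pd <- .pdist_families(seqm, rep(L, G))
      subsets <- combn(length(ref), 4L)
      counts <- matrix(0L, ncol(subsets), 4L)
      for (g in seq_len(G)) {
        d <- .square_from_pairs(kimura_correct(pd$p[, g]), pd$pairs, ref)
        nj <- .nj_core(d, ref, ref = ref)
        st <- .quartet_states(nj$masks, subsets)
        counts[cbind(seq_len(nrow(counts)), st)] <-
          counts[cbind(seq_len(nrow(counts)), st)] + 1L
      }
      w <- counts[, 1:3, drop = FALSE]
      top <- pmax(w[, 1], w[, 2], w[, 3])
      state <- max.col(w, ties.method = "first")
      runner <- vapply(seq_len(nrow(w)), function(i) max(w[i, -state[i]]), numeric(1))
      und <- (top == runner) | (top == 0)
      margin <- ifelse(und, 0, top - runner)
      bat <- .topology_battery(ref)
      live <- !und
      scores <- as.numeric((bat$states[, live, drop = FALSE] ==
                              matrix(state[live], nrow(bat$states), sum(live),
                                     byrow = TRUE)) %*% margin[live])
      best <- max(scores)
      win <- which(scores == best)
      win <- win[order(bat$keys[win])][1]
      masks <- .normalize_masks(.split_masks(bat$cands[[win]], ref), full)
    } else if (m == "supermatrix-ML") {
      aln <- matrix(config$model$alphabet[seqm], nrow = nrow(seqm),
                    dimnames = list(rownames(seqm), NULL))
      tr <- exhaustive_ml_tree(aln, config$model)
      masks <- .normalize_masks(.split_masks(tr, ref), full)
    } else {
      abort(paste0("unknown method: ", m))
    }
    out[[m]] <- c(
      correct = setequal(masks, true_masks),
      f_sister_b = !is.na(cherry_mask) && cherry_mask %in% masks
    )
  }
  out
}

# ---- recovery sweep ---------------------------------------------------------

#' Run the topology-recovery sweep over HGT fractions
#'
#' For each grid value of the HGT fraction `h` and each replicate: simulate a
#' genome set on the configured species tree, replace the recipient ortholog
#' with the donor copy in `round(G h)` families, drop the donor, reconstruct
#' by each method (supermatrix: concatenated Kimura-NJ; quartet supertree:
#' per-gene NJ trees, embedded quartet tally, plurality, exhaustive
#' supertree), and score recovery of the correct restricted species-tree
#' topology plus whether the recipient `F` was placed as sister to `B`.
#' Replicate RNG streams are derived from the master seed and the grid
#' position, so reruns with one master seed are byte-identical and grid
#' points are independent.
#'
#' @param config An [experiment_config()].
#' @param h_grid HGT fractions to test (default 0 to 0.6 in steps of 0.05).
#' @param methods Reconstruction methods.
#' @param replicates Replicates per grid point (default from config).
#' @param seed Master seed (default from config).
#' @return Tibble of class `recovery_table`: `b`, `h`, `method`,
#'   `replicates`, `n_correct`, `recovery_freq`, `n_f_sister_b`,
#'   `f_sister_b_freq`.
#' @export
run_recovery_sweep <- function(config, h_grid = seq(0, 0.6, by = 0.05),
                               methods = config$methods,
                               replicates = config$replicates,
                               seed = config$seed) {
  if (any(h_grid < 0 | h_grid > 1)) abort("h_grid values must lie in [0, 1]")
  rows <- list()
  for (gi in seq_along(h_grid)) {
    h <- h_grid[gi]
    tally <- matrix(0L, length(methods), 2L,
                    dimnames = list(methods, c("correct", "f_sister_b")))
    for (r in seq_len(replicates)) {
      rep_seed <- (abs(seed) + 1000003 * gi + 7919 * r) %% 2147483647
      set.seed(rep_seed)
      res <- .run_replicate(config, h, methods)
      for (m in methods) tally[m, ] <- tally[m, ] + res[[m]]
    }
    for (m in methods) {
      rows[[length(rows) + 1L]] <- tibble(
        b = config$b, h = h, method = m, replicates = as.integer(replicates),
        n_correct = as.integer(tally[m, "correct"]),
        recovery_freq = tally[m, "correct"] / replicates,
        n_f_sister_b = as.integer(tally[m, "f_sister_b"]),
        f_sister_b_freq = tally[m, "f_sister_b"] / replicates
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_table", class(out))
  attr(out, "seed") <- seed
  out
}

#' Threshold summary of a recovery sweep
#'
#' Per branch length and method: the largest grid `h` whose recovery
#' frequency exceeds `majority_cut` ("last success"), the smallest `h` at or
#' below the cut ("first failure", `NA` when none on the grid), and the
#' smallest `h` at which `F` lands sister to `B` in a majority of
#' replicates.
#'
#' @param table A `recovery_table` (grid need not be sorted).
#' @param majority_cut Majority threshold (default 0.5).
#' @return Tibble of class `recovery_summary` with columns `b`, `method`,
#'   `last_success`, `first_failure`, `first_f_sister_b`.
#' @export
summarize_recovery <- function(table, majority_cut = 0.5) {
  if (!nrow(table)) abort("empty recovery table")
  tab <- dplyr::arrange(tibble::as_tibble(table), .data$b, .data$method, .data$h)
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$b, .data$method),
    last_success = if (any(.data$recovery_freq > majority_cut))
      max(.data$h[.data$recovery_freq > majority_cut]) else NA_real_,
    first_failure = if (any(.data$recovery_freq <= majority_cut))
      min(.data$h[.data$recovery_freq <= majority_cut]) else NA_real_,
    first_f_sister_b = if (any(.data$f_sister_b_freq > majority_cut))
      min(.data$h[.data$f_sister_b_freq > majority_cut]) else NA_real_,
    .groups = "drop"
  )
  class(out) <- c("recovery_summary", class(out))
  attr(out, "majority_cut") <- majority_cut
  out
}

# ---- tidyverse verbs --------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.recovery_table <- function(x, ...) tibble::as_tibble(unclass(x)[names(x)])

#' @exportS3Method generics::glance
glance.recovery_table <- function(x, majority_cut = 0.5, ...) {
  tibble::as_tibble(summarize_recovery(x, majority_cut))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Recovery-versus-HGT curve
#'
#' @param object A `recovery_table`.
#' @param ... Unused.
#' @return A ggplot: recovery frequency against the HGT fraction, one line
#'   per method, faceted by the focal branch length.
#' @exportS3Method ggplot2::autoplot
autoplot.recovery_table <- function(object, ...) {
  d <- tidy.recovery_table(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$h, y = .data$recovery_freq,
                                  colour = .data$method)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~b, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "HGT fraction h (genes transferred)",
                  y = "frequency of recovering the correct topology",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
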