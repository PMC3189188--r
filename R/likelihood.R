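# ---- Felsenstein pruning likelihood ----------------------------------------

# alignment to integer codes in model alphabet; NA for gaps/ambiguity
.aln_codes <- function(aln, model) {
  codes <- match(aln, model$alphabet)
  dim(codes) <- dim(aln)
  rownames(codes) <- rownames(aln)
  if (any(is.na(codes) & !(aln %in% c("-", ".", "?", "X", "x")))) {
    bad <- unique(aln[is.na(codes) & !(aln %in% c("-", ".", "?", "X", "x"))])
    abort(paste0("unknown residue(s) for model alphabet: ", paste(bad, collapse = " ")))
  }
  codes
}

# conditional likelihoods for one rate category; returns list(loglik_site)
.prune_loglik <- function(tree, codes, model, rate) {
  S <- length(model$alphabet)
  L <- ncol(codes)
  n <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- n + tr$Nnode
  partial <- vector("list", nnode)
  scale_log <- numeric(L)
  for (i in seq_len(n)) {
    m <- matrix(0, S, L)
    ci <- codes[tr$tip.label[i], ]
    known <- !is.na(ci)
    m[cbind(ci[known], which(known))] <- 1
    m[, !known] <- 1
    partial[[i]] <- m
  }
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- prob_matrix(model, tr$edge.length[e], rate = rate)
    up <- P %*% partial[[ch]]
    if (is.null(partial[[p]])) partial[[p]] <- up
    else partial[[p]] <- partial[[p]] * up
    # rescale to avoid underflow (fast column maxima via max.col)
    mm <- partial[[p]]
    mx <- mm[cbind(max.col(t(mm), ties.method = "first"), seq_len(L))]
    mx[mx == 0] <- 1
    partial[[p]] <- mm / rep(mx, each = S)
    scale_log <- scale_log + log(mx)
  }
  root <- n + 1L
  site_l <- as.numeric(model$freqs %*% partial[[root]])
  list(site_loglik = log(site_l) + scale_log, site_lik_scaled = site_l,
       scale_log = scale_log)
}

#' Log-likelihood of an alignment on a tree (pruning algorithm)
#'
#' Computes the Felsenstein pruning log-likelihood under the model, with
#' optional discrete-gamma rate categories and an invariant-site proportion
#' (both taken from the model object). For a reversible model the value is
#' invariant to the (arbitrary) rooting of an unrooted tree.
#'
#' @param tree A `phylo` with all branch lengths set.
#' @param aln Character matrix (taxa x sites); all tree taxa must be rows.
#' @param model A [substitution_model()].
#' @return Log-likelihood (numeric scalar).
#' @export
felsenstein_loglik <- function(tree, aln, model = substitution_model("JTT")) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("all branch lengths must be set")
  }
  if (ncol(aln) == 0L) abort("zero-length alignment")
  missing <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing)) abort(paste0("alignment missing taxa: ", paste(missing, collapse = ", ")))
  codes <- .aln_codes(aln[tree$tip.label, , drop = FALSE], model)
  L <- ncol(codes)
  k <- length(model$rates)
  if (k == 1L && model$p_inv == 0) {
    pr <- .prune_loglik(tree, codes, model, model$rates)
    return(sum(pr$site_loglik))
  }
  site_lik <- matrix(0, k, L)
  scale_logs <- matrix(0, k, L)
  for (i in seq_len(k)) {
    pr <- .prune_loglik(tree, codes, model, model$rates[i])
    site_lik[i, ] <- pr$site_lik_scaled
    scale_logs[i, ] <- pr$scale_log
  }
  # mixture across categories in log space (per-site log-sum-exp)
  lw <- log(model$rate_weights)
  site_log <- vapply(seq_len(L), function(s) {
    terms <- lw + log(site_lik[, s]) + scale_logs[, s]
    m <- max(terms)
    m + log(sum(exp(terms - m)))
  }, numeric(1))
  if (model$p_inv > 0) {
    # invariant-site component: only constant observed columns can be invariant
    const_state <- apply(codes, 2, function(col) {
      u <- unique(col[!is.na(col)])
      if (length(u) == 1L) u else NA_integer_
    })
    inv_log <- ifelse(is.na(const_state), -Inf, log(model$freqs[const_state]))
    site_log <- vapply(seq_len(L), function(s) {
      a <- log1p(-model$p_inv) + site_log[s]
      b <- log(model$p_inv) + inv_log[s]
      m <- max(a, b)
      if (!is.finite(m)) return(a)
      m + log(exp(a - m) + exp(b - m))
    }, numeric(1))
  }
  sum(site_log)
}

# ---- exhaustive small-scale ML ----------------------------------------------

# cyclic single-branch optimisation of branch lengths (Brent via optimize)
.optimise_branch_lengths <- function(tree, aln, model, max_sweeps = 50,
                                     rel_tol = 1e-6) {
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  ll <- felsenstein_loglik(tree, aln, model)
  for (sweep in seq_len(max_sweeps)) {
    prev <- ll
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        felsenstein_loglik(tree, aln, model)
      }
      opt <- optimize(f, c(1e-8, 10), maximum = TRUE, tol = 1e-6)
      if (opt$objective > ll) {
        tree$edge.length[e] <- opt$maximum
        ll <- opt$objective
      }
    }
    if (abs(ll - prev) < rel_tol * (abs(prev) + 1)) break
  }
  list(tree = tree, loglik = ll)
}

#' Exhaustive maximum-likelihood tree search
#'
#' Enumerates every resolved unrooted topology on the alignment's taxa (at
#' most 8 taxa, 10,395 topologies), optimises branch lengths per topology by
#' cyclic single-branch Brent optimisation, and returns the topology with
#' the highest log-likelihood. Ties are broken by canonical newick order.
#'
#' @param aln Character matrix (taxa x sites) with rownames.
#' @param model A [substitution_model()].
#' @param max_sweeps,rel_tol Branch-length optimisation controls.
#' @return A `phylo` tree with attribute `loglik`.
#' @export
exhaustive_ml_tree <- function(aln, model = substitution_model("JTT"),
                               max_sweeps = 50, rel_tol = 1e-6) {
  taxa_names <- rownames(aln)
  n <- length(taxa_names)
  if (n > 8L) {
    abort("exhaustive ML search supports at most 8 taxa; use neighbor_joining()")
  }
  if (n < 4L) abort("need at least 4 taxa for a resolved unrooted topology")
  cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa_names)
  best <- NULL; best_ll <- -Inf; best_key <- NULL
  for (ci in seq_along(cands)) {
    # index extraction, not iteration: multiPhylo stores tip labels centrally
    fit <- .optimise_branch_lengths(cands[[ci]], aln, model, max_sweeps, rel_tol)
    key <- .topology_key(fit$tree)
    better <- fit$loglik > best_ll + 1e-9 ||
      (abs(fit$loglik - best_ll) <= 1e-9 && !is.null(best_key) && key < best_key)
    if (is.null(best) || better) {
      best <- fit$tree; best_ll <- fit$loglik; best_key <- key
    }
  }
  attr(best, "loglik") <- best_ll
  best
}
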