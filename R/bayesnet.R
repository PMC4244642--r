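#' Class-rooted augmented network structure
#'
#' The network runs over the class node y plus M binary component nodes.
#' The class node is the parentless root and is a parent of every component
#' node; the learnable part of the structure is the set of augmenting edges
#' among component nodes, which must stay acyclic and respect a cap on the
#' number of augmenting parents per node. `bn_structure()` builds such a
#' structure from an edge list.
#'
#' @param region_ids Integer ids of the M component nodes (column order of
#'   the outcome table).
#' @param edges `NULL` (no augmenting edges), a two-column matrix/data frame
#'   of `from`/`to` region ids, or an M x M logical adjacency matrix
#'   (`[i, j]` = edge from node i to node j, in `region_ids` order).
#' @param max_parents Maximum number of augmenting parents per component
#'   node (the class parent does not count). Default 3, keeping conditional
#'   probability tables estimable from cohorts of a few hundred subjects.
#' @return Object of class `bn_structure`.
#' @export
bn_structure <- function(region_ids, edges = NULL, max_parents = 3L) {
  region_ids <- as.integer(region_ids)
  m <- length(region_ids)
  if (m < 1L) abort("at least one component node is required")
  if (anyDuplicated(region_ids)) abort("duplicate region ids")
  adj <- matrix(FALSE, m, m)
  if (!is.null(edges)) {
    if (is.matrix(edges) && is.logical(edges)) {
      stopifnot(all(dim(edges) == c(m, m)))
      adj <- edges
    } else {
      edges <- as.data.frame(edges)
      for (r in seq_len(nrow(edges))) {
        i <- match(as.integer(edges[[1]][r]), region_ids)
        j <- match(as.integer(edges[[2]][r]), region_ids)
        if (is.na(i) || is.na(j)) abort("edge references an unknown region id")
        adj[i, j] <- TRUE
      }
    }
  }
  diag(adj) <- FALSE
  st <- structure(list(region_ids = region_ids, adj = adj,
                       max_parents = as.integer(max_parents)),
                  class = "bn_structure")
  validate_structure(st)
  st
}

validate_structure <- function(st) {
  if (!is_acyclic(st$adj)) abort("augmenting edges contain a cycle")
  if (any(colSums(st$adj) > st$max_parents)) {
    abort("a node exceeds the augmenting-parent cap")
  }
  invisible(st)
}

# Kahn elimination; M is small so O(M^2) passes are fine.
is_acyclic <- function(adj) {
  alive <- rep(TRUE, nrow(adj))
  repeat {
    indeg <- colSums(adj[alive, , drop = FALSE])
    leaf <- alive & indeg == 0
    if (!any(leaf)) break
    alive[leaf] <- FALSE
    if (!any(alive)) return(TRUE)
  }
  !any(alive)
}

topological_order <- function(adj) {
  m <- nrow(adj)
  alive <- rep(TRUE, m)
  ord <- integer(0)
  while (any(alive)) {
    indeg <- colSums(adj[alive, , drop = FALSE])
    ready <- which(alive & indeg == 0)
    if (length(ready) == 0L) abort("cyclic graph has no topological order")
    ord <- c(ord, ready[1])
    alive[ready[1]] <- FALSE
  }
  ord
}

#' @export
print.bn_structure <- function(x, ...) {
  e <- which(x$adj, arr.ind = TRUE)
  cat(sprintf("<bn_structure> class root + %d component nodes, %d augmenting edge(s)\n",
              length(x$region_ids), nrow(e)))
  if (nrow(e) > 0) {
    cat(paste0("  z_", x$region_ids[e[, 1]], " -> z_", x$region_ids[e[, 2]],
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
format.bn_structure <- function(x, ...) {
  e <- which(x$adj, arr.ind = TRUE)
  if (nrow(e) == 0) return("(no augmenting edges)")
  paste0(x$region_ids[e[, 1]], "->", x$region_ids[e[, 2]], collapse = ",")
}

# ---- family sufficient statistics ------------------------------------------

# Parent-configuration index for node m: bits (y, augmenting parents in
# increasing node order), y most significant, bit = 1 iff value is +1.
# Row-major index into the CPT rows, 1-based.
config_index <- function(y, zpa) {
  k <- if (is.null(zpa)) 0L else ncol(zpa)
  idx <- (y == 1L) * 2^k
  if (k > 0L) {
    for (t in seq_len(k)) idx <- idx + (zpa[, t] == 1L) * 2^(k - t)
  }
  as.integer(idx) + 1L
}

# Maximized log-likelihood of one component family (0 log 0 = 0).
family_loglik <- function(z, y, zpa) {
  n_cfg <- 2L^(1L + (if (is.null(zpa)) 0L else ncol(zpa)))
  cfg <- config_index(y, zpa)
  tot <- tabulate(cfg, n_cfg)
  pos <- tabulate(cfg[z == 1L], n_cfg)
  neg <- tot - pos
  xlogx <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
  sum(xlogx(pos, tot) + xlogx(neg, tot))
}

family_score <- function(z, y, zpa, n) {
  k <- if (is.null(zpa)) 0L else ncol(zpa)
  family_loglik(z, y, zpa) - (2^(1 + k) / 2) * log(n)
}

class_score <- function(y, n) {
  npos <- sum(y == 1L)
  xl <- function(a) if (a > 0) a * log(a / n) else 0
  xl(npos) + xl(n - npos) - 0.5 * log(n)
}

#' BIC score of a structure on fully observed outcome data
#'
#' Computes the maximized log-likelihood of the outcome data under the
#' structure minus the penalty `(d / 2) log n`, where
#' `d = 1 + sum_m 2^(1 + |pa_m|)` counts the free conditional-probability
#' parameters (one per parent configuration per binary node, one for the
#' class prior). Larger is better. The score decomposes over node families,
#' which the Metropolis-Hastings search exploits by rescoring only the
#' families a move touches.
#'
#' @param structure A [bn_structure()].
#' @param outcomes Outcome tibble with labeled `y` and `z_<region_id>`
#'   columns matching the structure's nodes.
#' @return Scalar BIC score.
#' @export
bic_score <- function(structure, outcomes) {
  dat <- structure_data(structure, outcomes)
  sum(all_family_scores(structure, dat$z, dat$y))
}

structure_data <- function(structure, outcomes) {
  regs <- outcome_regions(outcomes)
  if (!setequal(regs, structure$region_ids)) {
    abort("outcome columns do not match the structure's component nodes")
  }
  z <- outcome_matrix(outcomes)[, match(structure$region_ids, regs), drop = FALSE]
  y <- as.integer(outcomes$y)
  if (anyNA(y)) abort("structure scoring requires labeled subjects (no NA y)")
  check_binary_pm1(y, "class labels")
  list(z = z, y = y)
}

# Vector of per-family BIC contributions: class family first, then one per
# component node.
all_family_scores <- function(structure, z, y) {
  n <- length(y)
  m <- length(structure$region_ids)
  out <- numeric(m + 1L)
  out[1] <- class_score(y, n)
  for (j in seq_len(m)) {
    pa <- which(structure$adj[, j])
    zpa <- if (length(pa) > 0) z[, pa, drop = FALSE] else NULL
    out[j + 1L] <- family_score(z[, j], y, zpa, n)
  }
  out
}

# ---- parameter estimation ---------------------------------------------------

#' Fit conditional probability tables
#'
#' Count-based estimation of all network parameters from fully observed
#' outcome data: each CPT entry is `(count + smoothing) / (total + 2 *
#' smoothing)` for its parent configuration. `smoothing = 0` gives the pure
#' maximum-likelihood estimate; the default `smoothing = 1` is the posterior
#' mean under a uniform prior (Laplace). Parent configurations never seen in
#' the data fall back to 0.5.
#'
#' @inheritParams bic_score
#' @param smoothing Non-negative pseudo-count.
#' @return Object of class `sc_bn`: the structure, `prior_pos`
#'   (`p(y = +1)`), and per-node tables `p(z = +1 | y, parents)` stored
#'   row-major over parent configurations (y most significant bit, then
#'   augmenting parents in increasing node order; bit 1 = value +1).
#' @export
fit_bn <- function(structure, outcomes, smoothing = 1) {
  stopifnot(smoothing >= 0)
  dat <- structure_data(structure, outcomes)
  z <- dat$z
  y <- dat$y
  n <- length(y)
  prior_pos <- (sum(y == 1L) + smoothing) / (n + 2 * smoothing)
  cpts <- lapply(seq_along(structure$region_ids), function(j) {
    pa <- which(structure$adj[, j])
    k <- length(pa)
    zpa <- if (k > 0) z[, pa, drop = FALSE] else NULL
    n_cfg <- 2L^(1L + k)
    cfg <- config_index(y, zpa)
    tot <- tabulate(cfg, n_cfg)
    pos <- tabulate(cfg[z[, j] == 1L], n_cfg)
    p1 <- (pos + smoothing) / (tot + 2 * smoothing)
    p1[tot == 0 & smoothing == 0] <- 0.5
    list(parents = pa, p1 = p1)
  })
  new_sc_bn(structure, prior_pos, cpts, smoothing = smoothing, n = n)
}

new_sc_bn <- function(structure, prior_pos, cpts, smoothing = NA_real_, n = NA_integer_) {
  stopifnot(prior_pos >= 0, prior_pos <= 1)
  for (cp in cpts) stopifnot(all(cp$p1 >= 0), all(cp$p1 <= 1))
  structure(list(structure = structure, prior_pos = prior_pos, cpts = cpts,
                 smoothing = smoothing, n = n),
            class = "sc_bn")
}

#' Construct a network model from explicit parameters
#'
#' Used to specify ground-truth generating networks for simulation and for
#' oracle checks. `cpt` entries give `p(z = +1 | configuration)` row-major
#' in the documented configuration order (see [fit_bn()]).
#'
#' @param structure A [bn_structure()].
#' @param prior_pos Class prior `p(y = +1)`.
#' @param p1 List with one numeric vector per component node, length
#'   `2^(1 + number of augmenting parents)`.
#' @return An `sc_bn`.
#' @export
bn_model <- function(structure, prior_pos, p1) {
  m <- length(structure$region_ids)
  stopifnot(length(p1) == m)
  cpts <- lapply(seq_len(m), function(j) {
    pa <- which(structure$adj[, j])
    stopifnot(length(p1[[j]]) == 2^(1 + length(pa)))
    list(parents = pa, p1 = as.numeric(p1[[j]]))
  })
  new_sc_bn(structure, prior_pos, cpts)
}

#' @export
print.sc_bn <- function(x, ...) {
  cat(sprintf("<sc_bn> %d component nodes, %d augmenting edge(s), p(y=+1) = %.3f\n",
              length(x$structure$region_ids), sum(x$structure$adj), x$prior_pos))
  invisible(x)
}

# ---- inference --------------------------------------------------------------

#' Log joint probability of a full configuration
#'
#' `log p(y) + sum_m log p(z_m | parents, y)` under the factorized model.
#' Zero-probability configurations return `-Inf`.
#'
#' @param model An `sc_bn`.
#' @param z Integer vector of component values in `{-1, +1}` (structure node
#'   order), or an n x M matrix of such rows.
#' @param y Class value(s) in `{-1, +1}`, recycled to the rows of `z`.
#' @return Numeric log-probability, one per row.
#' @export
log_joint <- function(model, z, y) {
  if (!is.matrix(z)) z <- matrix(as.integer(z), nrow = 1L)
  m <- length(model$structure$region_ids)
  if (ncol(z) != m) abort("z length does not match the number of component nodes")
  check_binary_pm1(z, "component values")
  y <- rep_len(as.integer(y), nrow(z))
  check_binary_pm1(y, "class values")
  lp <- ifelse(y == 1L, log(model$prior_pos), log1p(-model$prior_pos))
  for (j in seq_len(m)) {
    cp <- model$cpts[[j]]
    zpa <- if (length(cp$parents) > 0) z[, cp$parents, drop = FALSE] else NULL
    p1 <- cp$p1[config_index(y, zpa)]
    lp <- lp + ifelse(z[, j] == 1L, log(p1), log1p(-p1))
  }
  lp
}

#' Posterior probability of disease given component outcomes
#'
#' Exact inference: `p(y = +1 | z)` from the two joint evaluations via
#' Bayes' rule. With any smoothing the denominator cannot vanish.
#'
#' @inheritParams log_joint
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @export
posterior <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(as.integer(z), nrow = 1L)
  lp_pos <- log_joint(model, z, 1L)
  lp_neg <- log_joint(model, z, -1L)
  both_zero <- !is.finite(lp_pos) & !is.finite(lp_neg)
  if (any(both_zero)) abort("configuration has zero probability under both classes")
  1 / (1 + exp(lp_neg - lp_pos))
}

#' Classify outcome vectors with a fitted network
#'
#' Maximum-posterior classification; a posterior of exactly 0.5 maps to +1.
#' When given an outcome tibble, appends `bn_posterior` and `bn_label`
#' columns.
#'
#' @param object An `sc_bn`.
#' @param outcomes Outcome tibble with `z_<region_id>` columns, or a vector /
#'   matrix of component values in structure node order.
#' @param ... Unused.
#' @return The tibble with predictions appended, or an integer vector of
#'   labels for vector/matrix input.
#' @export
predict.sc_bn <- function(object, outcomes, ...) {
  if (is.data.frame(outcomes)) {
    regs <- outcome_regions(outcomes)
    z <- outcome_matrix(outcomes)[, match(object$structure$region_ids, regs),
                                  drop = FALSE]
    p <- posterior(object, z)
    return(dplyr::mutate(outcomes, bn_posterior = p,
                         bn_label = ifelse(p >= 0.5, 1L, -1L)))
  }
  p <- posterior(object, outcomes)
  ifelse(p >= 0.5, 1L, -1L)
}

# ---- structure search -------------------------------------------------------

# Legal single-edge moves from a structure: add / delete / reverse among
# component nodes, keeping acyclicity and the parent cap. Returns a matrix
# with columns op (1 add, 2 delete, 3 reverse), i, j.
legal_moves <- function(st) {
  adj <- st$adj
  m <- nrow(adj)
  indeg <- colSums(adj)
  moves <- vector("list", 3L)
  add <- which(!adj & !t(adj) & !diag(TRUE, m), arr.ind = TRUE)
  if (nrow(add) > 0) {
    ok <- vapply(seq_len(nrow(add)), function(r) {
      i <- add[r, 1]; j <- add[r, 2]
      if (indeg[j] >= st$max_parents) return(FALSE)
      a2 <- adj; a2[i, j] <- TRUE
      is_acyclic(a2)
    }, logical(1))
    if (any(ok)) moves[[1]] <- cbind(1L, add[ok, , drop = FALSE])
  }
  del <- which(adj, arr.ind = TRUE)
  if (nrow(del) > 0) {
    moves[[2]] <- cbind(2L, del)
    ok <- vapply(seq_len(nrow(del)), function(r) {
      i <- del[r, 1]; j <- del[r, 2]
      if (indeg[i] + 1L > st$max_parents) return(FALSE)
      a2 <- adj; a2[i, j] <- FALSE; a2[j, i] <- TRUE
      is_acyclic(a2)
    }, logical(1))
    if (any(ok)) moves[[3]] <- cbind(3L, del[ok, , drop = FALSE])
  }
  out <- do.call(rbind, moves[!vapply(moves, is.null, logical(1))])
  if (is.null(out)) out <- matrix(integer(0), 0, 3)
  colnames(out) <- c("op", "i", "j")
  out
}

apply_move <- function(st, move) {
  adj <- st$adj
  i <- move[2]; j <- move[3]
  if (move[1] == 1L) adj[i, j] <- TRUE
  else if (move[1] == 2L) adj[i, j] <- FALSE
  else { adj[i, j] <- FALSE; adj[j, i] <- TRUE }
  st$adj <- adj
  st
}

#' Propose a single-edge structure move
#'
#' Draws uniformly among the legal add/delete/reverse moves and returns the
#' candidate together with the forward and backward neighborhood sizes
#' needed for the Hastings correction.
#'
#' @param structure A [bn_structure()].
#' @return List with `candidate`, `move` (op/i/j), `n_forward`, `n_backward`.
#' @export
propose_move <- function(structure) {
  mv <- legal_moves(structure)
  if (nrow(mv) == 0L) abort("no legal structure move exists")
  pick <- mv[sample.int(nrow(mv), 1L), ]
  cand <- apply_move(structure, pick)
  list(candidate = cand, move = pick,
       n_forward = nrow(mv), n_backward = nrow(legal_moves(cand)))
}

#' Metropolis-Hastings search for the network structure
#'
#' Runs an MCMC chain over class-rooted augmented structures. From the
#' current structure a single-edge move is proposed uniformly among legal
#' moves and accepted with probability
#' `min(1, exp(score' - score) * N(G) / N(G'))`, where `N(.)` are the
#' neighborhood sizes — the exponentiated BIC acts as an unnormalized
#' posterior over structures. The chain starts from the empty augmenting
#' edge set (pure naive Bayes) and the best structure visited anywhere in
#' the chain is returned together with the full trace.
#'
#' @inheritParams bic_score
#' @param n_iter Total iterations (default 20000).
#' @param burn_in Initial iterations treated as warm-up in the trace
#'   diagnostics (default 2000); the best structure is tracked over the
#'   whole chain.
#' @param seed Integer seed making the whole chain reproducible; `NULL`
#'   uses the current RNG state.
#' @param max_parents Augmenting-parent cap (default 3).
#' @param max_nodes Refuse more component nodes than this (default 10): the
#'   structure space grows super-exponentially and chain mixing degrades.
#' @param window Sliding-window width for the acceptance-ratio diagnostic.
#' @return Object of class `sc_bn_search`: `best_structure`, `best_score`,
#'   `final_structure`, `trace` (tibble: iteration, score, accepted,
#'   acceptance_ratio), `n`, `seed`.
#' @export
mh_structure_search <- function(outcomes, n_iter = 20000L, burn_in = 2000L,
                                seed = NULL, max_parents = 3L,
                                max_nodes = 10L, window = 500L) {
  regs <- outcome_regions(outcomes)
  if (length(regs) > max_nodes) {
    abort(sprintf(paste0(
      "%d component nodes exceed the cap of %d: the constrained-DAG space ",
      "grows super-exponentially and the chain will not mix"),
      length(regs), max_nodes))
  }
  if (n_iter < burn_in) abort("n_iter must be at least burn_in")
  if (!is.null(seed)) set.seed(seed)
  st <- bn_structure(regs, max_parents = max_parents)
  dat <- structure_data(st, outcomes)
  z <- dat$z; y <- dat$y; n <- length(y)

  fam <- all_family_scores(st, z, y)
  score <- sum(fam)
  best_st <- st; best_score <- score
  if (length(regs) == 1L) {
    # a single component node has no augmenting-edge moves
    return(structure(
      list(best_structure = st, best_score = score, final_structure = st,
           trace = tibble::tibble(iteration = integer(0), score = numeric(0),
                                  accepted = logical(0),
                                  acceptance_ratio = numeric(0)),
           n = n, seed = seed, burn_in = burn_in),
      class = "sc_bn_search"))
  }
  scores <- numeric(n_iter); acc <- logical(n_iter); ratio <- numeric(n_iter)

  rescore_family <- function(st, j) {
    pa <- which(st$adj[, j])
    zpa <- if (length(pa) > 0) z[, pa, drop = FALSE] else NULL
    family_score(z[, j], y, zpa, n)
  }

  for (it in seq_len(n_iter)) {
    prop <- propose_move(st)
    touched <- if (prop$move[1] == 3L) c(prop$move[2], prop$move[3]) else prop$move[3]
    fam_new <- fam
    for (j in touched) fam_new[j + 1L] <- rescore_family(prop$candidate, j)
    score_new <- sum(fam_new)
    log_alpha <- (score_new - score) + log(prop$n_forward) - log(prop$n_backward)
    if (log(runif(1)) < log_alpha) {
      st <- prop$candidate; fam <- fam_new; score <- score_new
      acc[it] <- TRUE
    }
    scores[it] <- score
    lo <- max(1L, it - window + 1L)
    ratio[it] <- mean(acc[lo:it])
    if (score > best_score) {
      best_score <- score; best_st <- st
    }
  }
  structure(
    list(best_structure = best_st, best_score = best_score,
         final_structure = st,
         trace = tibble::tibble(iteration = seq_len(n_iter), score = scores,
                                accepted = acc, acceptance_ratio = ratio),
         n = n, seed = seed, burn_in = burn_in),
    class = "sc_bn_search"
  )
}

#' @export
print.sc_bn_search <- function(x, ...) {
  cat(sprintf("<sc_bn_search> best BIC %.3f, %d augmenting edge(s), %d iterations\n",
              x$best_score, sum(x$best_structure$adj), nrow(x$trace)))
  invisible(x)
}

#' Exhaustive structure search over all constrained DAGs
#'
#' Enumerates every acyclic augmenting-edge set (respecting the parent cap)
#' and returns the BIC optimum. Feasible only for a handful of nodes; used
#' as the exact reference the stochastic search is validated against.
#'
#' @inheritParams mh_structure_search
#' @return List with `best_structure`, `best_score`, and `scores` (tibble of
#'   every structure's edge set and score).
#' @export
exhaustive_structure_search <- function(outcomes, max_parents = 3L) {
  regs <- outcome_regions(outcomes)
  m <- length(regs)
  if (m > 4L) abort("exhaustive enumeration supported only for up to 4 nodes")
  pairs <- which(!diag(TRUE, m), arr.ind = TRUE)  # ordered pairs, m(m-1)
  np <- nrow(pairs)
  st0 <- bn_structure(regs, max_parents = max_parents)
  dat <- structure_data(st0, outcomes)
  best <- NULL; best_score <- -Inf
  all_scores <- list()
  for (code in 0:(2^np - 1)) {
    bits <- bitwAnd(bitwShiftR(code, seq_len(np) - 1L), 1L) == 1L
    adj <- matrix(FALSE, m, m)
    adj[pairs[bits, , drop = FALSE]] <- TRUE
    if (any(adj & t(adj))) next
    if (any(colSums(adj) > max_parents)) next
    if (!is_acyclic(adj)) next
    st <- st0; st$adj <- adj
    sc <- sum(all_family_scores(st, dat$z, dat$y))
    all_scores[[length(all_scores) + 1L]] <- tibble::tibble(
      edges = format.bn_structure(st), score = sc)
    if (sc > best_score) { best_score <- sc; best <- st }
  }
  list(best_structure = best, best_score = best_score,
       scores = purrr::list_rbind(all_scores))
}

# ---- broom-style accessors --------------------------------------------------

#' Tidy a fitted network
#'
#' @param x An `sc_bn`.
#' @param ... Unused.
#' @return Tibble with one row per CPT entry: `region_id`, `parents`
#'   (comma-separated augmenting-parent region ids), `y`, parent value
#'   string, and `p_pos` (`p(z = +1 | config)`).
#' @exportS3Method generics::tidy
#' @export
tidy.sc_bn <- function(x, ...) {
  regs <- x$structure$region_ids
  purrr::map2(seq_along(regs), x$cpts, function(j, cp) {
    k <- length(cp$parents)
    n_cfg <- 2^(1 + k)
    idx <- seq_len(n_cfg) - 1L
    ybit <- idx %/% 2^k
    pa_str <- vapply(idx, function(v) {
      if (k == 0) return("")
      bits <- bitwAnd(bitwShiftR(v, k - seq_len(k)), 1L)
      paste(ifelse(bits == 1L, "+1", "-1"), collapse = ",")
    }, character(1))
    tibble::tibble(
      region_id = regs[j],
      parents = paste(regs[cp$parents], collapse = ","),
      y = ifelse(ybit == 1L, 1L, -1L),
      parent_values = pa_str,
      p_pos = cp$p1
    )
  }) |> purrr::list_rbind()
}

#' @rdname tidy.sc_bn
#' @exportS3Method generics::glance
#' @export
glance.sc_bn <- function(x, ...) {
  tibble::tibble(
    nodes = length(x$structure$region_ids),
    augmenting_edges = sum(x$structure$adj),
    parameters = 1 + sum(vapply(x$cpts, function(cp) length(cp$p1), numeric(1))),
    prior_pos = x$prior_pos,
    smoothing = x$smoothing,
    n = x$n
  )
}

#' Tidy the edges of a structure or search result
#'
#' @param x A `bn_structure` or `sc_bn_search`.
#' @param ... Unused.
#' @return Tibble of directed augmenting edges (`from`, `to`, region ids).
#' @exportS3Method generics::tidy
#' @export
tidy.bn_structure <- function(x, ...) {
  e <- which(x$adj, arr.ind = TRUE)
  tibble::tibble(from = x$region_ids[e[, 1]], to = x$region_ids[e[, 2]])
}

#' @rdname tidy.bn_structure
#' @exportS3Method generics::tidy
#' @export
tidy.sc_bn_search <- function(x, ...) tidy(x$best_structure)

#' @rdname tidy.bn_structure
#' @exportS3Method generics::glance
#' @export
glance.sc_bn_search <- function(x, ...) {
  tibble::tibble(
    best_score = x$best_score,
    augmenting_edges = sum(x$best_structure$adj),
    iterations = nrow(x$trace),
    acceptance_ratio = x$trace$acceptance_ratio[nrow(x$trace)],
    n = x$n
  )
}

#' Plot the Metropolis-Hastings convergence diagnostic
#'
#' Sliding-window acceptance ratio and running BIC score over the chain,
#' the standard convergence picture for structure MCMC.
#'
#' @param object An `sc_bn_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sc_bn_search <- function(object, ...) {
  tr <- tidyr::pivot_longer(
    object$trace[c("iteration", "score", "acceptance_ratio")],
    -"iteration", names_to = "metric", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Structure search diagnostics")
}
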