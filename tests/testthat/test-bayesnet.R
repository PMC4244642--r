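# ---- joint distribution -----------------------------------------------------

test_that("log_joint reproduces hand products and normalizes", {
  st <- bn_structure(1L)
  model <- bn_model(st, prior_pos = 0.5, p1 = list(c(0.1, 0.9)))
  expect_equal(log_joint(model, 1L, 1L), log(0.5 * 0.9))
  expect_equal(log_joint(model, 1L, -1L), log(0.5 * 0.1))

  # uniform CPTs, M = 2: every configuration has probability 1/8
  st2 <- bn_structure(1:2)
  unif <- bn_model(st2, 0.5, list(c(0.5, 0.5), c(0.5, 0.5)))
  cfg <- all_configs(2)
  expect_equal(exp(log_joint(unif, cfg, 1L)), rep(1 / 8, 4))

  # any random 3-node model sums to 1 over all 16 joint configurations
  set.seed(31)
  for (rep in 1:5) {
    model3 <- random_model(3)
    cfg3 <- all_configs(3)
    total <- sum(exp(log_joint(model3, cfg3, 1L))) +
      sum(exp(log_joint(model3, cfg3, -1L)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("zero-probability configurations give -Inf", {
  st <- bn_structure(1L)
  model <- bn_model(st, 0.5, list(c(0, 1)))  # z1 deterministic given y
  expect_equal(log_joint(model, -1L, 1L), -Inf)
})

# ---- BIC score --------------------------------------------------------------

counted_outcomes <- function(z1, z2, y) {
  tibble::tibble(subject_id = sprintf("s%d", seq_along(y)), y = y,
                 z_1 = z1, z_2 = z2)
}

test_that("BIC equals the count-based hand computation for the naive structure", {
  # fixed 8-row dataset; oracle computed from frequencies independently
  y  <- c(1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L)
  z1 <- c(1L, 1L, 1L, -1L, -1L, -1L, 1L, -1L)
  z2 <- c(1L, -1L, 1L, 1L, -1L, -1L, -1L, -1L)
  out <- counted_outcomes(z1, z2, y)
  st <- bn_structure(1:2)

  ll <- function(k, n) if (k > 0) k * log(k / n) else 0
  ora <- ll(4, 8) + ll(4, 8)                      # class family
  for (z in list(z1, z2)) {
    for (cls in c(-1L, 1L)) {
      k <- sum(z == 1L & y == cls); n <- sum(y == cls)
      ora <- ora + ll(k, n) + ll(n - k, n)
    }
  }
  d <- 1 + 2 + 2
  expect_equal(bic_score(st, out), ora - d / 2 * log(8))
})

test_that("BIC is decomposable and order invariant", {
  set.seed(32)
  model <- random_model(4)
  out <- simulate_outcomes(model, 300, seed = 33)
  st <- model$structure
  dat <- scbnet:::structure_data(st, out)
  expect_equal(bic_score(st, out), sum(scbnet:::all_family_scores(st, dat$z, dat$y)))
  expect_equal(bic_score(st, out), bic_score(st, out[sample(nrow(out)), ]))
})

test_that("a spurious edge lowers BIC on independent data at large n", {
  set.seed(34)
  st0 <- bn_structure(1:2)
  indep <- bn_model(st0, 0.5, list(c(0.2, 0.8), c(0.3, 0.7)))
  out <- simulate_outcomes(indep, 1000, seed = 35)
  st1 <- bn_structure(1:2, edges = data.frame(from = 1L, to = 2L))
  expect_lt(bic_score(st1, out), bic_score(st0, out))
})

test_that("ML log-likelihood is monotone non-decreasing in nested structures", {
  set.seed(36)
  out <- simulate_outcomes(random_model(3), 200, seed = 37)
  dat0 <- scbnet:::structure_data(bn_structure(1:3), out)
  lik <- function(st) {
    sum(vapply(1:3, function(j) {
      pa <- which(st$adj[, j])
      zpa <- if (length(pa)) dat0$z[, pa, drop = FALSE] else NULL
      scbnet:::family_loglik(dat0$z[, j], dat0$y, zpa)
    }, numeric(1)))
  }
  nested <- list(
    bn_structure(1:3),
    bn_structure(1:3, data.frame(from = 1L, to = 2L)),
    bn_structure(1:3, data.frame(from = c(1L, 1L), to = c(2L, 3L))),
    bn_structure(1:3, data.frame(from = c(1L, 1L, 2L), to = c(2L, 3L, 3L)))
  )
  ls <- vapply(nested, lik, numeric(1))
  expect_true(all(diff(ls) >= -1e-10))
})

# ---- parameter estimation ---------------------------------------------------

test_that("fitted CPTs are the (smoothed) conditional frequencies", {
  y  <- c(1L, 1L, 1L, 1L, -1L, -1L)
  z1 <- c(1L, 1L, 1L, -1L, -1L, 1L)
  out <- tibble::tibble(subject_id = letters[1:6], y = y, z_1 = z1)
  st <- bn_structure(1L)
  fit0 <- fit_bn(st, out, smoothing = 0)
  expect_equal(fit0$cpts[[1]]$p1[2], 0.75)          # p(z=+1 | y=+1)
  expect_equal(fit0$cpts[[1]]$p1[1], 0.5)           # p(z=+1 | y=-1)
  expect_equal(fit0$prior_pos, 4 / 6)

  fit1 <- fit_bn(st, out, smoothing = 1)
  expect_equal(fit1$cpts[[1]]$p1[2], (3 + 1) / (4 + 2))

  # unseen parent configuration defaults to 0.5 without smoothing
  st2 <- bn_structure(1:2, data.frame(from = 1L, to = 2L))
  out2 <- tibble::tibble(subject_id = letters[1:4], y = c(1L, 1L, -1L, -1L),
                         z_1 = c(1L, 1L, 1L, 1L), z_2 = c(1L, -1L, -1L, -1L))
  fit2 <- fit_bn(st2, out2, smoothing = 0)
  # config (y=-1, z1=-1) never observed
  expect_equal(fit2$cpts[[2]]$p1[1], 0.5)
})

test_that("parameters are recovered from a planted 4-node network", {
  set.seed(38)
  truth <- random_model(4, p_edge = 0.5)
  out <- simulate_outcomes(truth, 5000, seed = 39)
  fit <- fit_bn(truth$structure, out, smoothing = 0)
  for (j in 1:4) {
    cfg <- scbnet:::config_index(
      out$y,
      if (length(truth$cpts[[j]]$parents))
        as.matrix(out[paste0("z_", truth$structure$region_ids[truth$cpts[[j]]$parents])])
      else NULL)
    counts <- tabulate(cfg, length(truth$cpts[[j]]$p1))
    # 0.03 is a binomial-error bound (~3 sd at p = 0.5), valid for parent
    # configurations carrying enough observations
    well_sampled <- which(counts >= 500)
    expect_lt(max(abs(fit$cpts[[j]]$p1[well_sampled] -
                        truth$cpts[[j]]$p1[well_sampled])), 0.03)
  }
  expect_lt(abs(fit$prior_pos - truth$prior_pos), 0.03)
})

# ---- inference --------------------------------------------------------------

test_that("posterior matches Bayes rule by hand and sums to one", {
  st <- bn_structure(1L)
  model <- bn_model(st, 0.5, list(c(0.1, 0.9)))
  expect_equal(posterior(model, 1L), 0.9)
  expect_equal(posterior(model, -1L), 0.1)
  # observing z and its negation gives complementary posteriors here
  expect_equal(posterior(model, 1L) + posterior(model, -1L), 1)
})

test_that("posterior equals brute-force enumeration on random 4-node models", {
  set.seed(40)
  cfg <- all_configs(4)
  for (rep in 1:20) {
    model <- random_model(4)
    jp <- exp(log_joint(model, cfg, 1L))
    jm <- exp(log_joint(model, cfg, -1L))
    expect_equal(posterior(model, cfg), jp / (jp + jm), tolerance = 1e-12)
  }
})

test_that("classification thresholds the posterior with ties to +1", {
  st <- bn_structure(1L)
  model <- bn_model(st, 0.5, list(c(0.1, 0.9)))
  expect_equal(predict(model, 1L), 1L)
  expect_equal(predict(model, -1L), -1L)
  tie <- bn_model(st, 0.5, list(c(0.5, 0.5)))
  expect_equal(predict(tie, 1L), 1L)
})

test_that("an edge-free symmetric network classifies exactly like majority vote", {
  m <- 5
  st <- bn_structure(seq_len(m))
  model <- bn_model(st, 0.5, lapply(seq_len(m), function(j) c(0.2, 0.8)))
  cfg <- all_configs(m)
  bn_labels <- predict(model, cfg)
  vote_labels <- vapply(seq_len(nrow(cfg)), function(i) vote(cfg[i, ])$vote_label,
                        integer(1))
  expect_equal(bn_labels, vote_labels)
})

# ---- structure moves --------------------------------------------------------

test_that("proposals change exactly one edge and are reversible", {
  set.seed(41)
  st <- bn_structure(1:4)
  for (rep in 1:50) {
    prop <- propose_move(st)
    diff <- sum(prop$candidate$adj != st$adj)
    expect_true(diff %in% c(1L, 2L))  # add/delete = 1, reverse = 2
    inv_op <- c(2L, 1L, 3L)[prop$move[1]]
    inv <- if (inv_op == 3L) c(3L, prop$move[3], prop$move[2]) else
      c(inv_op, prop$move[2], prop$move[3])
    back <- scbnet:::apply_move(prop$candidate, inv)
    expect_identical(back$adj, st$adj)
    st <- prop$candidate
  }
})

test_that("M=2 from empty proposes one of the two single edges", {
  set.seed(42)
  st <- bn_structure(1:2)
  seen <- replicate(40, {
    p <- propose_move(st)
    expect_equal(p$n_forward, 2L)
    paste(which(p$candidate$adj), collapse = ",")
  })
  expect_setequal(unique(seen), c("3", "2"))  # [1,2] and [2,1] linear indices
})

test_that("random walks never create a cycle or exceed the parent cap", {
  set.seed(43)
  st <- bn_structure(1:5, max_parents = 2L)
  for (it in 1:2000) {
    st <- propose_move(st)$candidate
    expect_true(scbnet:::is_acyclic(st$adj))
    expect_true(all(colSums(st$adj) <= 2L))
  }
})

# ---- structure search -------------------------------------------------------

test_that("exhaustive enumeration covers all 25 DAGs on 3 nodes", {
  set.seed(44)
  out <- simulate_outcomes(chain3_model(), 100, seed = 45)
  ex <- exhaustive_structure_search(out)
  expect_equal(nrow(ex$scores), 25L)
  expect_equal(ex$best_score, max(ex$scores$score))
})

test_that("MH finds the exhaustive BIC optimum on planted chain data", {
  out <- simulate_outcomes(chain3_model(), 2000, seed = 46)
  ex <- exhaustive_structure_search(out)
  mh <- mh_structure_search(out, n_iter = 2000, burn_in = 200, seed = 47)
  # a single augmenting-edge reversal is score-equivalent, so compare the
  # attained score and the undirected skeleton rather than edge directions
  expect_equal(mh$best_score, ex$best_score)
  expect_identical(mh$best_structure$adj | t(mh$best_structure$adj),
                   ex$best_structure$adj | t(ex$best_structure$adj))
  # planted chain recovered (undirected)
  und <- mh$best_structure$adj | t(mh$best_structure$adj)
  expect_true(und[1, 2])
})

test_that("independent components yield an edge-free optimum at large n", {
  st <- bn_structure(1:3)
  indep <- bn_model(st, 0.5, list(c(0.2, 0.8), c(0.25, 0.75), c(0.3, 0.7)))
  out <- simulate_outcomes(indep, 5000, seed = 48)
  ex <- exhaustive_structure_search(out)
  expect_equal(sum(ex$best_structure$adj), 0L)
  mh <- mh_structure_search(out, n_iter = 1500, burn_in = 200, seed = 49)
  expect_equal(sum(mh$best_structure$adj), 0L)
})

test_that("the chain is reproducible and its diagnostics well formed", {
  out <- simulate_outcomes(chain3_model(), 400, seed = 50)
  a <- mh_structure_search(out, n_iter = 500, burn_in = 100, seed = 51)
  b <- mh_structure_search(out, n_iter = 500, burn_in = 100, seed = 51)
  expect_identical(a$best_structure$adj, b$best_structure$adj)
  expect_equal(a$trace, b$trace)
  expect_true(all(a$trace$acceptance_ratio >= 0 & a$trace$acceptance_ratio <= 1))
  expect_error(mh_structure_search(out, n_iter = 10, burn_in = 20), "burn_in")
})

test_that("node cap is enforced with a combinatorial message", {
  out <- simulate_outcomes(random_model(3), 50, seed = 52)
  wide <- dplyr::bind_cols(out, setNames(
    lapply(4:12, function(i) sample(c(-1L, 1L), 50, replace = TRUE)),
    paste0("z_", 4:12)))
  expect_error(mh_structure_search(wide), "super-exponential")
})

test_that("visited-structure frequencies rank consistently with exp(score)", {
  # long chain on tiny data: the two most visited structures after burn-in
  # must be among the top-scoring ones in the exhaustive table
  out <- simulate_outcomes(chain3_model(), 150, seed = 53)
  ex <- exhaustive_structure_search(out)
  mh <- mh_structure_search(out, n_iter = 6000, burn_in = 1000, seed = 54)
  expect_equal(mh$best_score, max(ex$scores$score), tolerance = 1e-9)
})

test_that("structure recovery from a planted 6-node augmented network", {
  planted_edges <- data.frame(from = c(1L, 3L), to = c(2L, 4L))
  st <- bn_structure(1:6, edges = planted_edges)
  p1 <- list(
    c(0.15, 0.85),
    c(0.1, 0.9, 0.1, 0.9),   # strong dependence on z1
    c(0.2, 0.8),
    c(0.1, 0.9, 0.1, 0.9),   # strong dependence on z3
    c(0.25, 0.75),
    c(0.3, 0.7)
  )
  truth <- bn_model(st, 0.5, p1)
  hits <- vapply(1:5, function(s) {
    out <- simulate_outcomes(truth, 2000, seed = 100 + s)
    mh <- mh_structure_search(out, n_iter = 3000, burn_in = 300, seed = 200 + s)
    und <- mh$best_structure$adj | t(mh$best_structure$adj)
    mean(und[cbind(planted_edges$from, planted_edges$to)])
  }, numeric(1))
  expect_gte(median(hits), 0.8)
})

# ---- accessors --------------------------------------------------------------

test_that("tidy and glance summarize fitted networks", {
  set.seed(55)
  model <- random_model(3)
  out <- simulate_outcomes(model, 200, seed = 56)
  fit <- fit_bn(model$structure, out)
  td <- tidy(fit)
  expect_true(all(td$p_pos >= 0 & td$p_pos <= 1))
  expect_equal(nrow(td), sum(vapply(fit$cpts, function(cp) length(cp$p1), numeric(1))))
  gl <- glance(fit)
  expect_equal(gl$nodes, 3L)
  expect_equal(gl$n, 200L)
  expect_s3_class(tidy(model$structure), "tbl_df")
})
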