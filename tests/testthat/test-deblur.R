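test_that("init_consensus keeps in-frame mass and normalizes", {
  p <- riboclear:::new_length_profile("T", 28L, 0L, c(4, 1, 1, 2, 0, 0))
  v <- init_consensus(p)
  expect_equal(as.numeric(v), c(4, 0, 0, 2, 0, 0) / 6)
  # already in frame 0: shape unchanged
  p2 <- riboclear:::new_length_profile("T", 28L, 0L, c(3, 0, 0, 9, 0, 0))
  expect_equal(as.numeric(init_consensus(p2)), c(3, 0, 0, 9, 0, 0) / 12)
  # only off-frame mass: degenerate
  p3 <- riboclear:::new_length_profile("T", 28L, 0L, c(0, 5, 0, 0, 2, 0))
  expect_error(init_consensus(p3), "in-frame")
  expect_error(init_consensus(riboclear:::new_length_profile("T", 27L, 0L,
                                                             c(1, 0, 0))),
               "28")
})

test_that("m_step solves the damped normal equations exactly", {
  # oracle: dense (A'A + I)^{-1} A'r computed with base linear algebra
  set.seed(13)
  for (trial in 1:20) {
    n <- sample(10:30, 1)
    l <- sample(c(26L, 28L, 31L), 1)
    w <- runif(31); w <- w / sum(w)
    cons <- runif(n); cons <- cons / sum(cons)
    p_obs <- runif(n); p_obs <- p_obs / sum(p_obs)
    p <- riboclear:::new_length_profile("T", l, 0L, p_obs, alpha = 1)
    b <- riboclear:::new_blur_vector(l, w)
    eps <- m_step(cons, p, b)
    A <- sapply(seq_len(n), function(j) {
      e <- numeric(n); e[j] <- 1; convolve_blur(e, w)
    })
    cs <- shift_profile(cons, riboclear:::obs_shift(l))
    r <- drop(A %*% cs) - p_obs
    oracle <- solve(crossprod(A) + diag(n), crossprod(A, r))
    expect_lt(max(abs(eps - drop(oracle))), 1e-8)
  }
})

test_that("m_step zero residual and linearity properties", {
  set.seed(14)
  n <- 40
  w <- riboclear:::blur_kernel(0L, 1.5)
  cons <- runif(n); cons <- cons / sum(cons)
  b <- riboclear:::new_blur_vector(28L, w)
  exact <- riboclear:::new_length_profile("T", 28L, 0L,
                                          convolve_blur(cons, w), alpha = 1)
  expect_lt(max(abs(m_step(cons, exact, b))), 1e-12)
  # doubling the residual doubles epsilon (p2 stays non-negative)
  base <- convolve_blur(cons, w)
  u <- runif(n, 0, 0.1)
  r1 <- m_step(cons, riboclear:::new_length_profile("T", 28L, 0L, base + u, 1), b)
  r2 <- m_step(cons, riboclear:::new_length_profile("T", 28L, 0L, base + 2 * u, 1), b)
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
})

test_that("e_step averages, cancels, clips and renormalizes", {
  cons <- c(0.3, 0, 0, 0, 0.7, 0, 0, 0, 0)
  zero <- list("28" = numeric(9))
  expect_equal(as.numeric(e_step(cons, zero, c("28" = 5))), cons)
  # two lengths, alpha (1,1), deviations that cancel at consensus cell 5:
  # obs index j = i + s_l with s_25 = +3, s_31 = -3
  devs <- list("25" = c(0, 0, 0, 0, 0, 0, 0, 0.2, 0),
               "31" = c(0, -0.2, 0, 0, 0, 0, 0, 0, 0))
  out <- e_step(cons, devs, c("25" = 1, "31" = 1))
  expect_equal(as.numeric(out), cons)
  # a deviation driving one cell negative is clipped before renormalization
  dev2 <- list("28" = c(0.4, rep(0, 8)))
  out2 <- e_step(cons, dev2, c("28" = 1))
  expect_equal(as.numeric(out2), c(0, 0, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(attr(out2, "pre_clip")[1], -0.1)
  expect_error(e_step(c(0.5, 0.5), list("28" = c(1, 1)), c("28" = 1)),
               "annihilated")
})

test_that("deblur objective matches a termwise oracle and reduces with eps=0", {
  set.seed(15)
  n <- 30
  lens <- c("27", "28")
  profs <- list(); devs <- list(); blurs <- list()
  for (nm in lens) {
    v <- runif(n); profs[[nm]] <- v / sum(v)
    devs[[nm]] <- rnorm(n, 0, 0.01)
    w <- runif(31); blurs[[nm]] <- w / sum(w)
  }
  alphas <- c("27" = 3, "28" = 7)
  cons <- runif(n); cons <- cons / sum(cons)
  obj <- deblur_objective(cons, devs, profs, blurs, alphas)
  oracle <- 0
  for (nm in lens) {
    cs <- shift_profile(cons, riboclear:::obs_shift(as.integer(nm)))
    fitv <- numeric(n)
    for (j in -15:15) {
      wj <- blurs[[nm]][j + 16]
      src <- cs - devs[[nm]]
      for (i in seq_len(n)) {
        k <- i - j
        if (k >= 1 && k <= n) fitv[i] <- fitv[i] + wj * src[k]
      }
    }
    oracle <- oracle + alphas[[nm]] *
      (sum((profs[[nm]] - fitv)^2) + sum(devs[[nm]]^2))
  }
  expect_equal(obj, oracle, tolerance = 1e-12)
  # zero deviations: reduces to the pure data-misfit term; perfect model -> 0
  zero_devs <- lapply(devs, function(d) numeric(n))
  perfect <- lapply(lens, function(nm)
    convolve_blur(shift_profile(cons, riboclear:::obs_shift(as.integer(nm))),
                  blurs[[nm]]))
  names(perfect) <- lens
  expect_equal(deblur_objective(cons, zero_devs, perfect, blurs, alphas), 0)
})

test_that("deblur_transcript: identity blurs give the aligned weighted average", {
  ps <- toy_profile_set()
  blurs <- list("28" = delta_blur(28L), "29" = delta_blur(29L))
  res <- deblur_transcript(ps, blurs)
  expect_true(res$converged)
  # with identity blurs and p29 = p28 shifted by -1, all lengths agree after
  # alignment; the consensus converges onto the common aligned profile
  aligned <- normalize_profile(ps$profiles[["28"]])$counts
  expect_gt(cor(res$consensus, aligned), 0.99)
})

test_that("deblur_transcript recovers synthetic truth and is monotone", {
  w <- module_world()
  bf <- module_blurfit()
  sets <- filter_profiles(w$profiles, w$ann)
  expect_gt(length(sets), 10)
  rs <- vapply(sets, function(ps) {
    res <- deblur_transcript(ps, bf$fit$blurs)
    tr <- res$objective_trace
    expect_true(all(tr$after_m <= tr$before + 1e-9))
    expect_true(all(tr$after_e_pre <= tr$after_m + 1e-9))
    expect_true(all(is.finite(unlist(tr[-1]))))
    expect_equal(sum(res$consensus), 1, tolerance = 1e-9)
    expect_true(all(res$consensus >= 0))
    cor(res$consensus, w$truth$transcripts[[ps$transcript_id]]$consensus)
  }, 0)
  expect_gt(median(rs), 0.9)
})

test_that("recovered per-length signals are more consistent than raw profiles", {
  w <- module_world()
  bf <- module_blurfit()
  sets <- filter_profiles(w$profiles, w$ann)
  better <- 0L; total <- 0L
  for (ps in sets[seq_len(min(8, length(sets)))]) {
    res <- deblur_transcript(ps, bf$fit$blurs)
    for (nm in names(res$per_length)) {
      s_l <- riboclear:::obs_shift(as.integer(nm))
      cons_obs <- shift_profile(res$consensus, s_l)
      r_true <- cor(res$per_length[[nm]]$p_true, cons_obs)
      r_raw <- cor(normalize_profile(ps$profiles[[nm]])$counts, cons_obs)
      total <- total + 1L
      if (r_true >= r_raw) better <- better + 1L
    }
  }
  expect_gt(better / total, 0.9)
})
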