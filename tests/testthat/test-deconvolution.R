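# small shared fixture: clean 3-type instance with true profiles
deconv_fix <- function() fixture("deconv_small", function() {
  ref <- make_reference(3, 60, 300, frac_nuclei = 0, seed = 51)
  sp <- make_spots(ref$truth, n_spots = 80, seed = 52, ambient_scale = 0.1)
  prof <- reference_profile(ref$truth$rho, ref$truth$theta)
  model <- build_deconv_model(prof, sp$dataset, deconv_model_spec("mouse"))
  fit <- fit_deconvolution(model, fit_config(n_steps = 700, seed = 1),
                           run_presence = FALSE)
  list(ref = ref, sp = sp, prof = prof, model = model, fit = fit)
})

test_that("the model mean reduces to the library-scaled mixture", {
  fx <- deconv_fix()
  m <- fx$model; d <- m$data
  nu <- matrix(1 / 4, d$S, 4) # 3 types + RBC
  lat <- list(nu = nu, bias = rep(0, d$G),
              background = rep(1e-12, d$G), foreground = rep(1, d$S),
              theta = rep(5, d$G),
              rbc_rho = rep(1e-12, length(d$hb_idx)),
              comp_rho = fx$prof$rho["Hepatocyte", d$comp_idx])
  rho_eff <- d$rho_base
  rho_eff[d$rbc_idx, d$hb_idx] <- 1e-12
  rho_eff[d$hep_idx, d$comp_idx] <- fx$prof$rho["Hepatocyte", d$comp_idx]
  want <- (nu %*% rho_eff) * d$lib
  ll <- m$log_joint(lat, d)
  direct <- sum(dnbinom(d$counts, size = 5, mu = pmax(want + 1e-12, 1e-8),
                        log = TRUE))
  expect_equal(ll,
               direct + sum(dnorm(0, 0, 1, log = TRUE) * d$G) +
                 sum(dnorm(log(rep(1e-12, d$G)), d$bg_prior_mu, d$bg_prior_sd,
                           log = TRUE)) +
                 sum(dnorm(log(rep(5, d$G)), 0, 5, log = TRUE)) +
                 sum(dnorm(log(rep(1e-12, length(d$hb_idx))), 0, 5, log = TRUE)) +
                 sum(dnorm(log(fx$prof$rho["Hepatocyte", d$comp_idx]), 0, 5,
                           log = TRUE)),
               tolerance = 1e-6)
})

test_that("analytic model gradients match finite differences", {
  fx <- deconv_fix()
  m <- fx$model; d <- m$data
  set.seed(3)
  lat <- list()
  for (l in m$latents) {
    u <- spotzone:::.shape_array(rnorm(prod(l$dim), 0, 0.3), l$dim)
    lat[[l$name]] <- l$transform$forward(u + l$init_loc)
  }
  g <- m$grad_log_joint(lat, d)
  for (nm in names(g)) {
    idx <- sample(length(lat[[nm]]), min(3, length(lat[[nm]])))
    for (i in idx) {
      h <- 1e-5 * max(abs(lat[[nm]][i]), 1e-3)
      lp <- lat; lp[[nm]][i] <- lp[[nm]][i] + h
      lm <- lat; lm[[nm]][i] <- lm[[nm]][i] - h
      fd <- (m$log_joint(lp, d) - m$log_joint(lm, d)) / (2 * h)
      expect_lt(abs(fd - g[[nm]][i]) / max(abs(fd), 1), 1e-4)
    }
  }
})

test_that("a pure-type deep spot maximizes the log-joint near nu = 1", {
  ref <- make_reference(3, 60, 300, frac_nuclei = 0, seed = 53)
  rho <- ref$truth$rho
  set.seed(54)
  lib <- 1e4
  kc <- rnbinom(ncol(rho), size = 10, mu = rho["KC", ] * lib)
  grid <- simplex_grid(3, step = 0.05)
  ll <- apply(grid, 1, function(nu) {
    mu <- as.numeric(nu %*% rho) * lib
    sum(dnbinom(kc, size = 10, mu = pmax(mu, 1e-8), log = TRUE))
  })
  best <- grid[which.max(ll), ]
  expect_gt(best[2], 0.9) # KC is the second row of the profile matrix
})

test_that("an inert RBC component leaves the log-joint unchanged", {
  fx <- deconv_fix()
  m <- fx$model; d <- m$data
  lat <- list(nu = matrix(c(0.3, 0.3, 0.4, 0), d$S, 4, byrow = TRUE),
              bias = rep(0, d$G), background = rep(0.01, d$G),
              foreground = rep(0.9, d$S), theta = rep(10, d$G),
              rbc_rho = rep(1e-15, length(d$hb_idx)),
              comp_rho = fx$prof$rho["Hepatocyte", d$comp_idx])
  ll_with <- m$log_joint(lat, d)
  # structurally disable the component: zero proportion AND zero profile
  d2 <- d; d2$rbc_enabled <- FALSE
  lat2 <- lat; lat2$rbc_rho <- NULL
  ll_without <- m$log_joint(lat2, d2)
  prior_term <- sum(dnorm(log(rep(1e-15, length(d$hb_idx))), 0, 5, log = TRUE))
  expect_lt(abs((ll_with - prior_term) - ll_without), 1e-6)
})

test_that("missing hemoglobin genes disable the RBC pseudo-type with a warning", {
  fx <- deconv_fix()
  keep <- setdiff(fx$prof$genes, hemoglobin_genes("mouse"))
  prof2 <- subset_reference(fx$prof, keep)
  ds <- fx$sp$dataset
  ds$counts <- ds$counts[, keep]
  ds$genes <- keep
  ds$lib <- rowSums(ds$counts)
  expect_warning(m2 <- build_deconv_model(prof2, ds, deconv_model_spec("mouse")),
                 "RBC pseudo-type disabled")
  expect_false("RBC" %in% m2$deconv$type_names)
})

test_that("E[nu] agrees with the dense grid-search ML oracle", {
  ref <- make_reference(3, 60, 300, frac_nuclei = 0, seed = 55)
  # clean instance: no bias, background, foreground loss or zonation
  sp <- make_spots(ref$truth, n_spots = 20, seed = 56, ambient_scale = 0,
                   bias_sd = 0, fg_shape1 = 1e6, fg_shape2 = 1e-6,
                   lib_meanlog = 10)
  prof <- reference_profile(ref$truth$rho, ref$truth$theta)
  model <- build_deconv_model(prof, sp$dataset, deconv_model_spec("mouse"),
                              estimate_nuisances = FALSE)
  fit <- fit_deconvolution(model, fit_config(n_steps = 1500, seed = 1),
                           run_presence = FALSE)
  ct <- colnames(sp$truth$nu)
  nu_hat <- fit$nu[, ct] / rowSums(fit$nu[, ct])
  grid <- simplex_grid(3, step = 0.02)
  rho <- ref$truth$rho
  th <- sp$truth$theta_gene
  for (s in seq_len(20)) {
    ll <- apply(grid, 1, function(nu) {
      mu <- as.numeric(nu %*% rho) * sp$dataset$lib[s]
      sum(dnbinom(sp$dataset$counts[s, ], size = th, mu = pmax(mu, 1e-8),
                  log = TRUE))
    })
    oracle <- grid[which.max(ll), ]
    expect_lt(sum(abs(nu_hat[s, ] - oracle)), 0.1)
  }
})

test_that("two seeds give consistent proportion estimates", {
  fx <- deconv_fix()
  fit2 <- fit_deconvolution(fx$model, fit_config(n_steps = 700, seed = 2),
                            run_presence = FALSE)
  l1 <- mean(rowSums(abs(fx$fit$nu - fit2$nu)))
  expect_lt(l1, 0.05)
})

test_that("planted capture bias is recovered in sign", {
  ref <- make_reference(4, 100, 400, frac_nuclei = 0, seed = 57)
  planted <- setNames(rep(0.5, 10),
                      grep("^Gene", colnames(ref$counts), value = TRUE)[1:10])
  sp <- make_spots(ref$truth, n_spots = 250, seed = 58, bias_sd = 0.15,
                   planted_bias = planted)
  prof <- reference_profile(ref$truth$rho, ref$truth$theta)
  model <- build_deconv_model(prof, sp$dataset, deconv_model_spec("mouse"))
  fit <- fit_deconvolution(model, fit_config(n_steps = 1200, seed = 1),
                           run_presence = FALSE)
  rec <- fit$capture_bias[names(planted)] - median(fit$capture_bias)
  expect_gte(sum(rec > 0), 9)
})

test_that("zeroing an absent type leaves the likelihood ratio near zero", {
  ref <- make_reference(3, 60, 300, frac_nuclei = 0, seed = 59)
  sp <- make_spots(ref$truth, n_spots = 40, absent_celltypes = "LSEC",
                   seed = 60)
  prof <- reference_profile(ref$truth$rho, ref$truth$theta)
  model <- build_deconv_model(prof, sp$dataset, deconv_model_spec("mouse"))
  fit <- fit_deconvolution(model, fit_config(n_steps = 700, seed = 1),
                           run_presence = FALSE)
  lr <- presence_test(fit, model, celltype = "LSEC", n_mc = 50, seed = 2)
  expect_lt(max(abs(lr)), 10)
  expect_lt(median(abs(lr)), 2)
  expect_error(presence_test(fit, model, celltype = "Astrocyte"),
               "unknown cell type")
})

test_that("abundance_table is tidy, consistent and CSV-stable", {
  ref <- make_reference(3, 60, 300, frac_nuclei = 0, seed = 61)
  sp <- make_spots(ref$truth, n_spots = 40, seed = 62)
  prof <- reference_profile(ref$truth$rho, ref$truth$theta)
  model <- build_deconv_model(prof, sp$dataset, deconv_model_spec("mouse"))
  fit <- fit_deconvolution(model,
                           fit_config(n_steps = 400, seed = 1),
                           run_presence = TRUE)
  tab <- abundance_table(fit)
  nu_cols <- grep("^nu_", names(tab))
  expect_equal(rowSums(tab[, nu_cols]), rep(1, nrow(tab)), tolerance = 1e-6)
  pr_cols <- grep("^present_", names(tab))
  expect_identical(unname(as.matrix(tab[, pr_cols])),
                   unname(fit$presence_logLR > fit$threshold))
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(as.matrix(back[, nu_cols]), unname(as.matrix(tab[, nu_cols])),
               tolerance = 1e-9, ignore_attr = TRUE)
})
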