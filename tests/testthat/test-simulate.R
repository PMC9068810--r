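test_that("no-process limit keeps the resident bound for the whole movie", {
  p <- competition_params(k_arrival = 0, k_passive = 0)
  log <- simulate_molecule(p, duration = 300, flow_time = 10, rng_seed = 1)
  expect_equal(as.data.frame(log),
               data.frame(time_s = 0, species = "resident", action = "bind"),
               ignore_attr = TRUE)
  iv <- event_log_intervals(log)
  expect_equal(iv$t_start, 0)
  expect_equal(iv$t_end, 300)
  expect_true(iv$right_censored)
})

test_that("passive-only survival matches the analytic exponential", {
  p <- competition_params(k_arrival = 0, k_passive = 0.01)
  set.seed(101)
  n <- 10000
  still_bound <- vapply(seq_len(n), function(i) {
    log <- simulate_molecule(p, duration = 300, flow_time = 10)
    !any(log$species == "resident" & log$action == "dissociate")
  }, logical(1))
  p_true <- exp(-0.01 * 300)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(still_bound) - p_true), 3 * se)
})

test_that("displacement delays follow the configured exponential", {
  p <- competition_params(k_arrival = 0.5, p_probe = 0, p_displace = 1,
                          diss_mixture = list(c(1, 13)),
                          k_passive = 0, max_competitors = 1)
  set.seed(202)
  delays <- numeric(0)
  while (length(delays) < 10000) {
    log <- simulate_molecule(p, duration = 600, flow_time = 0)
    arr <- log$time_s[log$species == "competitor_1" & log$action == "bind"]
    dep <- log$time_s[log$species == "resident" & log$action == "dissociate"]
    if (length(arr) && length(dep)) delays <- c(delays, dep - arr)
  }
  delays <- delays[seq_len(10000)]
  expect_lt(abs(mean(delays) - 13), 3 * 13 / sqrt(10000))
})

test_that("mixture validation rejects malformed configurations", {
  expect_error(competition_params(diss_mixture = list(c(0.5, 10), c(0.4, 1))),
               "sum to 1")
  expect_error(competition_params(p_probe = 1.2), "\\[0, 1\\]")
  expect_error(competition_params(diss_mixture = list(c(-0.1, 5), c(1.1, 5))),
               ">= 0")
})

test_that("event logs conserve bind/dissociate balance across presets", {
  set.seed(33)
  for (pair in c("H-DA_vs_DA", "H-DA_vs_CX", "H-CX_vs_DA", "H-CX_vs_CX")) {
    p <- competition_preset(pair)
    for (rep in 1:25) {
      log <- simulate_molecule(p, duration = 300, flow_time = 10)
      for (sp in unique(log$species)) {
        e <- log[log$species == sp, ]
        n_open <- sum(e$action == "bind") -
          sum(e$action %in% c("dissociate", "bleach"))
        expect_true(n_open %in% c(0L, 1L))
      }
      # concurrent competitor count never exceeds max_competitors
      ev <- log[log$species != "resident", ]
      delta <- ifelse(ev$action == "bind", 1L, -1L)
      if (nrow(ev))
        expect_lte(max(cumsum(delta[order(ev$time_s)])), p$max_competitors)
      expect_true(!is.unsorted(log$time_s))
    }
  }
})

test_that("identical seeds reproduce identical event logs and traces", {
  p <- competition_preset("H-DA_vs_CX")
  log1 <- simulate_molecule(p, 300, 10, rng_seed = 7)
  log2 <- simulate_molecule(p, 300, 10, rng_seed = 7)
  expect_identical(as.data.frame(log1), as.data.frame(log2))
  acq <- acquisition_params(noise_sd = 20)
  tr1 <- render_traces(log1, acq, rng_seed = 3)
  tr2 <- render_traces(log2, acq, rng_seed = 3)
  expect_identical(tr1$cy3$intensity, tr2$cy3$intensity)
  expect_identical(tr1$cy5$intensity, tr2$cy5$intensity)
})

test_that("noise-free traces are background plus unit times occupancy", {
  log <- make_log(list(list(0, "resident", "bind")), duration = 300)
  acq <- acquisition_params(noise_sd = 0, unit_intensity = 300,
                            background_pre = 100, background_post = 100)
  tr <- render_traces(log, acq)
  mask <- excitation_mask(acq)
  expect_true(all(tr$cy3$intensity[mask[, "cy3"]] == 400))
  expect_true(all(tr$cy3$intensity[!mask[, "cy3"]] == 100))

  # two simultaneously bound competitors: linear plateau at bg + 2 units
  log2 <- make_log(list(list(0, "resident", "bind"),
                        list(50, "competitor_1", "bind"),
                        list(60, "competitor_2", "bind"),
                        list(80, "competitor_1", "dissociate"),
                        list(80, "competitor_2", "dissociate")))
  acq2 <- acquisition_params(noise_sd = 0, background_pre = 100,
                             background_post = 160, flow_frame = 100)
  tr2 <- render_traces(log2, acq2)
  both <- tr2$cy5$excited & tr2$cy5$time_s >= 60.05 & tr2$cy5$time_s < 79.95
  expect_true(all(tr2$cy5$intensity[both] == 160 + 2 * 300))
  pre <- tr2$cy5$excited & tr2$cy5$time_s < 10
  expect_true(all(tr2$cy5$intensity[pre] == 100))
})

test_that("alternating excitation doubles the mean photobleaching time", {
  p <- competition_params(k_arrival = 0, k_passive = 0, k_bleach = 0.05)
  log <- simulate_molecule(p, duration = 300, flow_time = 10, rng_seed = 1)
  acq_alt <- acquisition_params(noise_sd = 0, both_on_head = 0,
                                both_on_tail = 0)
  acq_cont <- acquisition_params(noise_sd = 0, both_on_head = 3000,
                                 both_on_tail = 0)
  bleach_time <- function(acq, seed) {
    tr <- render_traces(log, acq, rng_seed = seed)
    aug <- attr(tr, "log")
    bt <- aug$time_s[aug$action == "bleach" & aug$species == "resident"]
    if (length(bt)) bt else NA_real_
  }
  set.seed(44)
  t_alt <- vapply(1:400, function(s) bleach_time(acq_alt, s), numeric(1))
  t_cont <- vapply(1:400, function(s) bleach_time(acq_cont, s + 1000),
                   numeric(1))
  # continuous excitation bleaches within the movie essentially always
  m_alt <- mean(t_alt, na.rm = TRUE)
  m_cont <- mean(t_cont, na.rm = TRUE)
  expect_gt(m_alt / m_cont, 1.6)
  expect_lt(m_alt / m_cont, 2.4)
})

test_that("movie rendering integrates to the trace rendering", {
  log <- make_log(list(list(0, "resident", "bind"),
                       list(30, "competitor_1", "bind")), duration = 60)
  acq <- acquisition_params(n_frames = 600, flow_frame = 100, noise_sd = 0,
                            field_size = c(32, 64), psf_sigma = 1.0)
  stack <- render_movie(list(log), acq, positions = cbind(15, 15))
  tr <- render_traces(log, acq)
  aoi <- data.frame(id = "aoi_1", x_cy3 = 15, y_cy3 = 15, x_cy5 = 47,
                    y_cy5 = 15, box_halfwidth = 3)
  got3 <- integrate_aoi(stack, aoi, "cy3", acq)
  # AOI-integrated signal = box_area * background + unit * PSF mass in box
  on3 <- got3$excited & got3$time_s > 1 & got3$time_s < 59
  sig <- got3$intensity[on3] - 49 * acq$background_pre
  expect_true(all(abs(sig - acq$unit_intensity) / acq$unit_intensity < 0.01))
  # signal-present frames track the trace rendering within PSF truncation
  ref <- tr$cy3$intensity[on3] - acq$background_pre
  expect_lt(max(abs(sig - ref)) / acq$unit_intensity, 0.01)
})

test_that("empty movies are pure background and identity mapping coincides", {
  acq <- acquisition_params(n_frames = 20, flow_frame = 5, noise_sd = 0,
                            field_size = c(16, 32))
  stack <- render_movie(list(), acq, positions = NULL)
  expect_equal(dim(stack), c(20, 16, 32))
  expect_true(all(stack[1, , 1:16] == acq$background_pre))
  expect_true(all(stack[20, , 17:32] == acq$background_post))
  # identity channel transform keeps Cy3 and Cy5 centres coincident
  acq_id <- acquisition_params(n_frames = 20, flow_frame = 5, noise_sd = 0,
                               field_size = c(16, 32),
                               channel_transform = list(A = diag(2),
                                                        b = c(0, 0)))
  log <- make_log(list(list(0, "resident", "bind")), duration = 2)
  stack2 <- render_movie(list(log), acq_id, positions = cbind(8, 8))
  expect_equal(attr(stack2, "positions_cy5"), attr(stack2, "positions"))
  expect_error(render_movie(list(log), acq, positions = cbind(200, 8)),
               "inside")
})
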