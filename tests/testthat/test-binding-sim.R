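# Time-based binding simulation: drive construction, three-step
# propagation, and the phrase/sentence contrast metrics.

test_that("templates satisfy their structural constraints", {
  for (tpl in list(phrase_template(), sentence_template())) {
    td <- tidy(tpl)
    expect_equal(sum(td$layer == "S"), 4)
    expect_true(all(td$n_children[td$layer == "S"] == 0))
    expect_true(all(td$kernel_ms[td$layer != "S"] %in% c(30, 250)))
    expect_equal(unname(td$cutoff_hz[td$layer == "PO"][1]), 50)
  }
  ph <- tidy(phrase_template()); se <- tidy(sentence_template())
  expect_gt(sum(se$layer != "S"), sum(ph$layer != "S"))
  expect_gte(sum(se$n_children == 2), sum(ph$n_children == 2))
})

test_that("YAML templates reproduce the built-in defaults", {
  p <- read_template(system.file("extdata", "phrase_template.yaml",
                                 package = "oscbind"))
  expect_equal(tidy(p), tidy(phrase_template()))
  s <- read_template(system.file("extdata", "sentence_template.yaml",
                                 package = "oscbind"))
  expect_equal(tidy(s), tidy(sentence_template()))
})

test_that("cyclic or malformed templates are rejected", {
  bad <- tibble::tibble(
    id = c("S1", "S2", "S3", "S4", "PO1", "RB1", "P1"),
    layer = c("S", "S", "S", "S", "PO", "RB", "P"),
    children = list(character(), character(), character(), character(),
                    c("S1", "RB1"), "PO1", c("RB1", "PO1"))
  )
  expect_error(oscbind:::new_structure_template("phrase", bad), "cycle")
})

test_that("noise-free drive bursts respect duration bounds and windows", {
  drive <- gen_drive(n_pairs = 3, fs = 1000, duration = 4, noise_sd = 0,
                     seed = 11)
  for (p in 1:3) {
    for (k in 1:4) {
      x <- drive$sequences[p, k, ]
      expect_equal(max(x), 1) # peak normalisation
      expect_true(all(x %in% c(0, 1)))
      for (sec in 0:3) {
        win <- x[(sec * 1000 + (k - 1) * 250) + 1:250]
        d <- sum(win)
        expect_gte(d, 140); expect_lte(d, 230)
        # burst contiguous inside its window
        on <- which(win == 1)
        expect_equal(on, seq(min(on), max(on)))
        # nothing outside the unit's windows
        other <- x[setdiff(seq_len(4000),
                           unlist(lapply(0:3, function(s) {
                             (s * 1000 + (k - 1) * 250) + 1:250
                           })))]
        expect_true(all(other == 0))
      }
    }
  }
})

test_that("drives are deterministic given the seed and noisy by default", {
  d1 <- gen_drive(2, seed = 5)
  d2 <- gen_drive(2, seed = 5)
  expect_identical(d1$sequences, d2$sequences)
  expect_equal(apply(d1$sequences, c(1, 2), max), matrix(1, 2, 4))
  expect_error(gen_drive(2, fs = 100), "fs")
})

test_that("causal boxcar matches a brute-force moving-average oracle", {
  set.seed(3)
  for (width in c(1, 7, 30)) {
    x <- rnorm(200)
    expect_equal(oscbind:::causal_moving_average(x, width),
                 oracle_moving_average(x, width), tolerance = 1e-10)
  }
  # unit step through a 30-sample window: linear ramp then plateau
  step <- rep(1, 100)
  y <- oscbind:::causal_moving_average(step, 30)
  expect_equal(y[1:30], (1:30) / 30)
  expect_true(all(y[31:100] == 1))
})

test_that("propagation normalises peaks and passes zero drive through", {
  drive <- gen_drive(2, fs = 1000, duration = 2, noise_sd = 0.2, seed = 2)
  acts <- propagate(sentence_template(), drive, pair = 1)
  for (id in setdiff(names(acts), c("S1", "S2", "S3", "S4"))) {
    expect_equal(max(abs(acts[[id]])), 1)
  }
  zero <- drive
  zero$sequences[] <- 0
  acts0 <- propagate(phrase_template(), zero, pair = 1)
  expect_true(all(vapply(acts0, function(a) all(a == 0), logical(1))))
})

test_that("identical activations in both conditions give zero t statistics", {
  drive <- gen_drive(4, fs = 1000, duration = 2, seed = 9)
  acts <- oscbind:::propagate_all(sentence_template(), drive)
  res <- sim_metrics(acts, acts,
                     templates = list(phrase = sentence_template(),
                                      sentence = sentence_template()),
                     seed = 1, n_rand = 30, n_draw = 3,
                     metrics = c("power", "phase_coherence", "phase_coupling"))
  deterministic <- res$tests$metric != "phase_coherence"
  expect_true(all(res$tests$t[deterministic] == 0))
  expect_true(all(res$tests$p.value[deterministic] == 1))
  # coherence randomizations are drawn independently per condition, so the
  # statistic fluctuates around zero instead of vanishing exactly
  expect_lt(abs(res$tests$t[!deterministic]), 5)
  expect_equal(res$tests$mean_sentence[!deterministic],
               res$tests$mean_phrase[!deterministic], tolerance = 0.05)
})

test_that("coherence of identical signals is exactly 1", {
  n_time <- 500
  base <- sin(2 * pi * 3 * (1:n_time) / 500) + 0.5
  acts <- list(PO1 = matrix(base, n_time, 40))
  attr(acts, "fs") <- 500
  attr(acts, "layers") <- c(PO1 = "PO")
  tpl <- list(nodes = tibble::tibble(id = "PO1", layer = "PO",
                                     children = list("S1")))
  res <- sim_metrics(acts, acts,
                     templates = list(phrase = tpl, sentence = tpl),
                     seed = 2, n_rand = 5, n_draw = 30,
                     metrics = "phase_coherence")
  expect_true(all(abs(res$coherence$coherence - 1) < 1e-9))
})

test_that("metric ranges hold on a small full run", {
  res <- run_binding_sim(n_pairs = 6, duration = 4, seed = 3)
  pw <- res$pairwise
  expect_true(all(pw$power >= 0))
  expect_true(all(pw$phase_coupling >= 0 & pw$phase_coupling <= 1))
  expect_true(all(pw$power_coupling >= -1 & pw$power_coupling <= 1))
  expect_true(all(res$coherence$coherence >= 0 & res$coherence$coherence <= 1))
  expect_equal(nrow(tidy(res)), 4)
  expect_true(is.logical(glance(res)$all_sentence_higher))
})
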