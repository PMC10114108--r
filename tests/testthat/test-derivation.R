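test_that("equivalized after-housing-cost income arithmetic", {
  expect_equal(equivalize_income(1000, 200, 1.0), 800)
  expect_equal(equivalize_income(1500, 300, 1.5), 800)
  expect_equal(equivalize_income(200, 300, 1.0), -100)  # retained, not clipped
  expect_error(equivalize_income(1000, 200, 0), "positive")
  expect_equal(oecd_scale(2, 1), 1.8)
})

test_that("poverty line is 60% of the wave median", {
  expect_equal(poverty_line(c(100, 200, 300, 400, 500)), 180)
  expect_equal(poverty_line(rep(250, 7)), 150)
  expect_equal(poverty_line(c(100, 200, 300, 400)), 150)  # even-count median
  expect_error(poverty_line(c(NA_real_, NA_real_)), "non-missing")
})

test_that("poverty derivation uses a strict threshold per wave", {
  pan <- data.frame(person_id = 1:5, wave = 1L,
                    income = c(100, 200, 300, 400, 500),
                    housing_costs = 0, n_adults = 1L, n_children = 0L)
  d <- derive_poverty(pan)
  expect_equal(d$a, c(1L, 0L, 0L, 0L, 0L))  # line 180, only 100 below

  # equal incomes: nobody is poor (ties at the line are unexposed)
  pan2 <- data.frame(person_id = 1:4, wave = 1L, income = 1000,
                     housing_costs = 0, n_adults = 1L, n_children = 0L)
  expect_equal(derive_poverty(pan2)$a, rep(0L, 4))

  # the same income can flip exposure across waves with different medians
  pan3 <- data.frame(
    person_id = rep(1:5, 2), wave = rep(1:2, each = 5),
    income = c(160, 250, 300, 350, 400,    # wave 1 median 300, line 180
               160, 100, 150, 200, 120),   # wave 2 median 150, line 90
    housing_costs = 0, n_adults = 1L, n_children = 0L)
  d3 <- derive_poverty(pan3)
  inc160 <- d3[d3$income == 160, ]
  expect_equal(inc160$a[inc160$wave == 1], 1L)
  expect_equal(inc160$a[inc160$wave == 2], 0L)
})

test_that("GHQ-12 caseness boundary sits at a score of four", {
  expect_equal(derive_caseness(4L), 1L)
  expect_equal(derive_caseness(3L), 0L)
  expect_equal(derive_caseness(c(0L, 12L)), c(0L, 1L))
  expect_error(derive_caseness(13L), "range")
  expect_error(derive_caseness(-1L), "range")
})

test_that("analysis table joins lags on consecutive observed waves only", {
  tp <- toy_panel()
  tp <- derive_poverty(tp)
  tab <- build_analysis_table(tp)
  # persons observed waves 1-3 contribute rows at t = 2, 3
  expect_equal(nrow(tab), 4)
  expect_equal(tab$wave, c(2L, 3L, 2L, 3L))
  expect_equal(tab$y_lag, c(0L, 1L, 0L, 1L))

  # a person observed in a single wave contributes nothing
  solo <- tp[tp$person_id == 1 & tp$wave == 2, ]
  solo$person_id <- 99L
  expect_equal(nrow(build_analysis_table(rbind(tp[0, ], solo))), 0)

  # a skipped wave breaks the lag chain: person 1 observed at waves 1 and 3
  # has no consecutive pair left and contributes no analysis rows
  gap <- tp[!(tp$person_id == 1 & tp$wave == 2), ]
  tab_gap <- build_analysis_table(gap)
  expect_equal(nrow(tab_gap[tab_gap$person_id == 1, ]), 0)
  expect_equal(tab_gap$wave[tab_gap$person_id == 2], c(2L, 3L))

  expect_error(build_analysis_table(rbind(tp, tp[1, ])), "duplicate")
})

test_that("complete n x T panel yields n(T-1) analysis rows", {
  cfg <- clean_cfg(150, 5, seed = 4)
  p <- generate_panel(cfg)
  p <- derive_poverty(p)
  tab <- build_analysis_table(p)
  aged_out <- sum(p$age > 64 & p$wave >= 2)
  expect_equal(nrow(tab), 150 * 4 - aged_out)
})

test_that("age eligibility is applied per wave at time t", {
  tp <- derive_poverty(toy_panel())
  tp$age[tp$person_id == 2] <- c(63L, 64L, 65L)
  tab <- build_analysis_table(tp)
  # person 2: wave 2 (age 64) kept, wave 3 (age 65) dropped
  expect_equal(tab$wave[tab$person_id == 2], 2L)
})

test_that("transition tables implement the reference-group restrictions", {
  tab <- data.frame(person_id = 1:6, wave = 2L,
                    a = c(1L, 0L, 1L, 0L, 1L, 0L),
                    a_lag = c(0L, 0L, 1L, 1L, 0L, 1L),
                    ghq_case = 0L)
  into <- derive_transitions(tab, "into")
  expect_true(all(into$a_lag == 0))
  expect_equal(into$exposure, c(1L, 0L, 1L))  # (0,1)->1, (0,0)->0
  outof <- derive_transitions(tab, "outof")
  expect_true(all(outof$a_lag == 1))
  expect_equal(outof$exposure, c(0L, 1L, 1L))  # (1,1)->0, (0,1)->1
  # partition identity
  expect_equal(nrow(into) + nrow(outof), nrow(tab))
  # degenerate input: empty restriction is error-free
  all_poor <- tab[tab$a_lag == 1, ]
  expect_equal(nrow(derive_transitions(all_poor, "into")), 0)
  expect_error(derive_transitions(tab, "sideways"))
})

test_that("poverty derivation is invariant to person-id relabeling", {
  cfg <- clean_cfg(300, 3, seed = 17)
  p <- generate_panel(cfg)
  q <- p; q$person_id <- q$person_id + 1000L
  expect_equal(derive_poverty(q)$a, derive_poverty(p)$a)
})
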