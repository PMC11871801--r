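# diary with fully scripted counts: participant P01 has 2 contacts every
# day; P02 has 5 on each window-a weekday and 0 elsewhere
scripted_diary <- function() {
  cal <- survey_calendar()
  participants <- make_participants(age = c(30, 8), sex = c("female", "male"),
                                    hh = c(2, 4), region = c("Seoul", "Busan"))
  days <- cal$days$date
  contacts <- dplyr::bind_rows(
    purrr::map(days, ~ make_contact("P01", .x, n = 2L)),
    purrr::map(days[cal$days$period == "I"],
               ~ make_contact("P02", .x, contact_age = 8, n = 5L)))
  survey_diary(participants, contacts, default_population(), cal)
}

test_that("marginal means reproduce hand-computable unit cases", {
  d <- scripted_diary()
  # P01: mean 2, constant; participant-level sd across one participant is NA
  m1 <- marginal_mean(d, "age", "30-39")
  expect_equal(m1$mean, 2)
  expect_equal(m1$n, 1L)
  # P02: 5 contacts on 5 of 14 days -> mean 25/14
  m2 <- marginal_mean(d, "age", "5-9")
  expect_equal(m2$mean, 25 / 14)
  # two participants with per-participant means 3 and 5 average to 4
  expect_equal(crude_ratio(4, 4), 1)
  cal2 <- short_calendar(n_a = 1L, n_b = 1L)
  p <- make_participants(age = c(20, 25), sex = c("female", "female"),
                         hh = c(1, 1), region = c("Seoul", "Seoul"))
  ct <- dplyr::bind_rows(
    make_contact("P01", "2023-12-06", n = 3L), make_contact("P01", "2024-02-07", n = 3L),
    make_contact("P02", "2023-12-06", n = 5L), make_contact("P02", "2024-02-07", n = 5L))
  d2 <- survey_diary(p, ct, default_population(), cal2)
  expect_equal(marginal_mean(d2, "age", "20-29")$mean, 4)
  expect_equal(marginal_mean(d2, "age", "20-29")$sd, stats::sd(c(3, 5)))
  expect_error(marginal_mean(d2, "age", "70+"),
               class = "contactdiaries_validation_error")
})

test_that("marginal means match an independent group-by computation", {
  d <- small_survey(n = 120, seed = 31L)
  counts <- daily_counts(d)
  for (cov in c("age", "sex", "household")) {
    tab <- marginal_means(d, cov)
    lev_of <- switch(cov,
      age = as.character(age_bin(d$participants$age_years)),
      sex = d$participants$sex,
      household = as.character(d$participants$household_size_class))
    # brute force: per-participant means, then aggregate by level
    pm <- tapply(counts$n_contacts, counts$participant_id, mean)
    pm <- pm[d$participants$participant_id]
    by_lev <- split(as.numeric(pm), lev_of)
    for (i in seq_len(nrow(tab))) {
      lv <- as.character(tab$level[i])
      if (!lv %in% names(by_lev)) next
      expect_equal(tab$marginal_mean[i], mean(by_lev[[lv]]))
      expect_equal(tab$marginal_sd[i], stats::sd(by_lev[[lv]]))
      expect_equal(tab$n_participants[i], length(by_lev[[lv]]))
    }
  }
  # period rows: pooled participant-day means, all participants in each row
  tabp <- marginal_means(d, "period")
  expect_true(all(tabp$n_participants == nrow(d$participants)))
  for (i in seq_len(nrow(tabp))) {
    sel <- counts$n_contacts[as.character(counts$period) == tabp$level[i]]
    expect_equal(tabp$marginal_mean[i], mean(sel))
    expect_equal(tabp$marginal_sd[i], stats::sd(sel))
  }
})

test_that("crude ratios reproduce the published worked examples", {
  # age 20-29 vs 0-4 and period III vs I marginal means
  expect_equal(round(crude_ratio(3.22, 5.67), 2), 0.57)
  expect_equal(round(crude_ratio(3.67, 5.49), 2), 0.67)
  expect_equal(crude_ratio(2.4, 2.4), 1)
  # scale invariance
  expect_equal(crude_ratio(3 * 1.7, 5 * 1.7), crude_ratio(3, 5))
  expect_error(crude_ratio(1, 0), class = "contactdiaries_validation_error")
})

test_that("overall mean is total contacts over participant-days", {
  expect_equal(round(contact_rate(133776, 1987, 14), 2), 4.81)
  d <- scripted_diary()
  expect_equal(overall_mean(d), (2 * 14 + 25) / (2 * 14))
  # zero contacts
  p <- make_participants()
  d0 <- survey_diary(p, make_contact("P01", "2023-12-06")[0, ],
                     default_population())
  expect_equal(overall_mean(d0), 0)
})

test_that("dispersion check uses the sample variance of participant-days", {
  cal <- short_calendar(n_a = 2L, n_b = 1L)
  p <- make_participants(age = 30, sex = "female", hh = 1, region = "Seoul")
  ct <- make_contact("P01", "2024-02-07", n = 6L)
  d <- survey_diary(p, ct, default_population(), cal)  # counts {0, 0, 6}
  dc <- dispersion_check(d)
  expect_equal(dc$mean, 2)
  expect_equal(dc$variance, 12)
  expect_equal(dc$ratio, 6)

  # constant counts: zero variance, zero ratio
  d2 <- scripted_diary()
  d2$contacts <- d2$contacts[d2$contacts$participant_id == "P01", ]
  d2$participants <- d2$participants[1, ]
  expect_equal(dispersion_check(d2)$ratio, 0)
})

test_that("composition tables conserve the period means and normalise", {
  d <- small_survey(n = 150, seed = 33L)
  periods <- marginal_means(d, "period")
  for (attr in c("relation", "duration", "residential_area", "contact_type")) {
    tab <- composition_table(d, attr)
    sums <- tapply(tab$proportion, tab$period, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    cells <- tapply(tab$mean_contacts, tab$period, sum)
    expect_equal(as.numeric(cells[periods$level]), periods$marginal_mean)
  }
  # brute-force cross-tab oracle for one attribute
  tab <- composition_table(d, "relation")
  period <- classify_period(d$contacts$date, d$calendar)
  days_per <- table(d$calendar$days$period)
  n <- nrow(d$participants)
  for (p in c("I", "IV")) {
    for (lv in relation_levels()) {
      manual <- sum(period == p & d$contacts$relation == lv) /
        (n * as.integer(days_per[p]))
      got <- tab$mean_contacts[tab$period == p & tab$level == lv]
      expect_equal(got, manual)
    }
  }
  # generator direction: period IV extended-family cell far above period I
  ef <- tab[tab$level == "extended_family", ]
  expect_gt(ef$mean_contacts[ef$period == "IV"],
            2 * ef$mean_contacts[ef$period == "I"])
})

test_that("cross-tabulated proportions are row-normalised and match table()", {
  d <- small_survey(n = 100, seed = 35L)
  m <- cross_tab_proportions(d, "duration", "relation", "I-II")
  rs <- rowSums(m, na.rm = TRUE)
  expect_true(all(abs(rs[!is.na(rs) & rs > 0] - 1) < 1e-12))
  # independent contingency computation
  period <- classify_period(d$contacts$date, d$calendar)
  sel <- period %in% c("I", "II")
  oracle <- prop.table(table(d$contacts$duration_class[sel],
                             d$contacts$relation[sel]), 1)
  expect_equal(m[duration_levels(), relation_levels()],
               matrix(as.numeric(oracle[duration_levels(), relation_levels()]),
                      nrow = 5, dimnames = list(duration_levels(),
                                                relation_levels())))

  # deterministic diary: every >4h contact cohabiting
  cal <- short_calendar()
  p <- make_participants(age = 30, sex = "female", hh = 2, region = "Seoul")
  ct <- dplyr::bind_rows(
    make_contact("P01", "2023-12-06", relation = "cohabiting", duration = ">4h", n = 3L),
    make_contact("P01", "2023-12-06", relation = "coworker", duration = "<5min", n = 2L))
  dd <- survey_diary(p, ct, default_population(), cal)
  m2 <- cross_tab_proportions(dd, "duration", "relation", "I-II")
  expect_equal(m2[">4h", "cohabiting"], 1)
  expect_error(cross_tab_proportions(dd, "duration", "relation", "III-IV"),
               class = "contactdiaries_validation_error")
})
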