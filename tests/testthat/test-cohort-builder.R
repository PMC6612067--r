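test_that("index visit is the first visit inside the enrolment window", {
  v <- make_visits(c("P1", "P1"), admission_date = c("2005-12-30", "2006-03-01"))
  idx <- find_index_visits(v, "2006-01-01", "2013-01-01")
  expect_equal(idx$index_date, as.Date("2006-03-01"))

  # the last enrolment day (strictly before the end bound) still qualifies
  v2 <- make_visits("P2", admission_date = "2012-12-31")
  idx2 <- find_index_visits(v2, "2006-01-01", "2013-01-01")
  expect_equal(idx2$index_date, as.Date("2012-12-31"))
  expect_equal(nrow(find_index_visits(
    make_visits("P3", admission_date = "2013-01-01"),
    "2006-01-01", "2013-01-01")), 0L)

  # same-day ties collapse to that date
  v3 <- make_visits(c("P4", "P4"), visit_type = c("ed", "soc"),
                    admission_date = "2006-05-05")
  expect_equal(find_index_visits(v3, "2006-01-01", "2013-01-01")$index_date,
               as.Date("2006-05-05"))
})

test_that("inclusion keeps patients aged 21 and above at index", {
  idx <- data.frame(patient_id = c("A", "B", "C"),
                    index_date = as.Date("2010-06-15"))
  pts <- make_patients(c("A", "B", "C"),
                       birth_date = c("1989-06-15",   # exactly 21
                                      "1989-06-16",   # 20 years 364 days
                                      "1950-01-01"))
  expect_setequal(apply_inclusion(pts, idx), c("A", "C"))

  # brute-force filter over a 10-patient fixture with 3 under-age
  ages <- c(25, 19, 40, 20.5, 33, 21, 67, 18, 50, 29)
  idx10 <- data.frame(patient_id = sprintf("Q%02d", 1:10),
                      index_date = as.Date("2010-01-01"))
  pts10 <- make_patients(idx10$patient_id,
                         birth_date = as.Date("2010-01-01") -
                           round(ages * 365.25) - 1)
  kept <- apply_inclusion(pts10, idx10)
  expect_length(kept, 7L)
  expect_setequal(kept, idx10$patient_id[ages >= 21])
})

test_that("window aggregation follows the stated attribution rules", {
  w <- build_windows(data.frame(patient_id = "P1",
                                index_date = as.Date("2006-01-01")))
  pts <- make_patients("P1")
  # two real admissions (LOS 3 and 4) plus one short stay:
  # admissions counts all three, LOS only the real ones
  v <- make_visits(rep("P1", 3), visit_type = "inpatient",
                   admission_date = c("2006-01-01", "2006-03-01", "2006-04-01"),
                   discharge_date = c("2006-01-04", "2006-03-05", "2006-04-01"),
                   short_stay = c(FALSE, FALSE, TRUE))
  a <- aggregate_window(v, w, pts, "year1")
  expect_equal(a$admissions, 3)
  expect_equal(a$los_total, 7)

  # a stay admitted on day 364 of year 1 belongs wholly to year 1
  v2 <- rbind(make_visits("P1", visit_type = "soc",
                          admission_date = "2006-01-01"),
              make_visits("P1", visit_type = "inpatient",
                          admission_date = "2006-12-31",
                          discharge_date = "2007-01-06"))
  a1 <- aggregate_window(v2, w, pts, "year1")
  a2 <- aggregate_window(v2, w, pts, "year2")
  expect_equal(a1$los_total, 6)
  expect_equal(a1$admissions, 1)
  expect_equal(a2$admissions, 0)

  # same-day non-short admission counts one day
  v3 <- make_visits("P1", visit_type = "inpatient",
                    admission_date = "2006-02-01",
                    discharge_date = "2006-02-01")
  expect_equal(aggregate_window(v3, w, pts, "year1")$los_total, 1)
})

test_that("mixed-setting fixture matches a per-visit summation oracle", {
  set.seed(42)
  n_pat <- 5
  ids <- sprintf("P%d", 1:n_pat)
  w <- build_windows(data.frame(patient_id = ids,
                                index_date = as.Date("2006-01-01")))
  pts <- make_patients(ids)
  rows <- list()
  for (p in ids) {
    k <- sample(2:6, 1)
    type <- sample(c("inpatient", "soc", "ed", "therapy"), k, TRUE)
    adm <- as.Date("2006-01-01") + sample(0:420, k, TRUE)
    los <- sample(0:9, k, TRUE)
    rows[[p]] <- make_visits(rep(p, k), visit_type = type,
                             admission_date = adm,
                             discharge_date = ifelse(type == "inpatient",
                                                     format(adm + los), NA),
                             cost = round(runif(k, 10, 5000), 2),
                             short_stay = type == "inpatient" & runif(k) < 0.3)
  }
  v <- do.call(rbind, rows)
  a <- aggregate_window(v, w, pts, "year1")
  for (p in ids) {
    inw <- v$patient_id == p & v$admission_date < as.Date("2007-01-01")
    vi <- v[inw, ]
    expect_equal(a$cost_total[a$patient_id == p], sum(vi$cost))
    expect_equal(a$admissions[a$patient_id == p],
                 sum(vi$visit_type == "inpatient"))
    real_ip <- vi$visit_type == "inpatient" & !vi$short_stay
    expect_equal(a$los_total[a$patient_id == p],
                 sum(pmax(1, as.numeric(vi$discharge_date - vi$admission_date))[real_ip]))
    expect_equal(a$soc_visits[a$patient_id == p], sum(vi$visit_type == "soc"))
    expect_equal(a$ed_attendances[a$patient_id == p], sum(vi$visit_type == "ed"))
  }
  # conservation: total cost over both windows equals total attributed cost
  a2 <- aggregate_window(v, w, pts, "year2")
  attributed <- v$admission_date < as.Date("2008-01-01")
  expect_equal(sum(a$cost_total) + sum(a2$cost_total), sum(v$cost[attributed]))
  # permutation invariance
  perm <- v[sample.int(nrow(v)), ]
  ap <- aggregate_window(perm, w, pts, "year1")
  expect_equal(ap[order(ap$patient_id), ], a[order(a$patient_id), ],
               ignore_attr = TRUE)
})

test_that("year-1 decedents have no year-2 aggregate", {
  ids <- c("P1", "P2")
  w <- build_windows(data.frame(patient_id = ids,
                                index_date = as.Date("2006-01-01")))
  pts <- make_patients(ids, death_date = c("2006-06-01", NA))
  v <- make_visits(ids, admission_date = "2006-02-01")
  a1 <- aggregate_window(v, w, pts, "year1")
  a2 <- aggregate_window(v, w, pts, "year2")
  expect_true(a1$died_in_window[a1$patient_id == "P1"])
  expect_false("P1" %in% a2$patient_id)
  expect_true("P2" %in% a2$patient_id)
})
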