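sched <- price_schedule()

test_that("currency conversion is exact, linear and guarded", {
  expect_equal(convert_currency(125.20, sched), 1)
  expect_equal(convert_currency(0, sched), 0)
  expect_equal(convert_currency(626.00, sched), 5)
  a <- 317.3; b <- 41.9
  expect_equal(convert_currency(a + b, sched),
               convert_currency(a, sched) + convert_currency(b, sched))
  expect_error(convert_currency(-1, sched), "non-negative")
})

test_that("indirect costs follow the human capital approach", {
  wage_sched <- price_schedule(minimum_wage = 1252)
  expect_equal(indirect_cost(0, 0, wage_sched), 0)
  expect_equal(indirect_cost(1, 0, wage_sched), 10)        # 1252 / 125.20
  expect_equal(indirect_cost(0, 2, wage_sched), 10)        # 2 half-days = 1 day
  expect_error(indirect_cost(-1, 0, wage_sched), "non-negative")
})

test_that("resource use is priced into the cost taxonomy", {
  zero_ru <- list(consultations = 0, screenings = 0, medication_spend_nrs = 0,
                  inpatient_admissions = 0, inpatient_nights = 0,
                  transport_trips = 0, food_servings = 0,
                  work_days_lost_inpatient = 0, half_days_outpatient = 0,
                  sessions_attended = 0, calls_received = 0,
                  minutes_per_call = 0, sms_received = 0)
  cb0 <- price_resource_use(zero_ru, sched)
  expect_equal(cb0$total, 0)
  expect_equal(cb0$intervention_total, 0)

  ru <- zero_ru
  ru$consultations <- 2; ru$screenings <- 1
  cb <- price_resource_use(ru, sched)
  expect_equal(cb$consultation, 2 * 250 / 125.20)  # 3.99 printed
  expect_equal(cb$screening, 5)
  expect_equal(cb$direct_medical_subtotal, 2 * 250 / 125.20 + 5)
  expect_equal(round(cb$direct_medical_subtotal, 2), 8.99)

  ru$inpatient_nights <- 2  # without an admission: invariant violation
  expect_error(price_resource_use(ru, sched), "inpatient_nights")

  ru$inpatient_nights <- 0
  bad <- ru; bad$screenings <- NULL
  expect_error(price_resource_use(bad, sched), "screenings")
})

test_that("intervention delivery costs split into phone, peer and training", {
  iv <- intervention_cost(sessions = 0, calls = 10, minutes_per_call = 3,
                          sms = 20, schedule = sched, participants_per_cluster = 16)
  expect_equal(iv$phone, (10 * 3 * 2 + 20 * 1) / 125.20)  # 0.64 printed
  zero <- intervention_cost(0, 0, 0, 0, sched, 16)
  expect_equal(zero$total, 0)
  expect_equal(c(zero$phone, zero$peer, zero$training), c(0, 0, 0))
  expect_error(intervention_cost(1, 1, 1, 1, sched, 0), ">= 1")

  # shared components divide per head
  iv8 <- intervention_cost(12, 5, 3, 10, sched, 8)
  iv16 <- intervention_cost(12, 5, 3, 10, sched, 16)
  expect_equal(iv8$peer, 2 * iv16$peer)
  expect_equal(iv8$training, 2 * iv16$training)

  # component means as printed sum to the printed intervention total
  cb <- cost_breakdown(list(consultation = 0, screening = 0, medication = 0,
                            inpatient = 0, transport = 0, food = 0,
                            indirect_income_loss = 0,
                            intervention_phone = 0.47, intervention_peer = 2.53,
                            intervention_training = 14.33))
  expect_equal(cb$intervention_total, 17.33)
})

test_that("cost breakdowns are additive and homogeneous in prices", {
  d <- generate_trial(small_config(seed = 31))
  cb <- participant_costs(d, sched)
  expect_equal(cb$direct_medical_subtotal,
               cb$consultation + cb$screening + cb$medication + cb$inpatient,
               tolerance = 1e-12)
  expect_equal(cb$total,
               cb$direct_medical_subtotal + cb$direct_non_medical_subtotal +
                 cb$indirect_income_loss + cb$intervention_total,
               tolerance = 1e-12)

  # doubling every unit price (and pass-through spend) doubles every cost
  k <- 2
  sched2 <- price_schedule(consultation = 250 * k, screening = 626 * k,
                           bed_day = 1500 * k, transport_trip = 50 * k,
                           food_serving = 30 * k, call_minute = 2 * k,
                           sms = 1 * k, trainer_session = 3000 * k,
                           peer_supporter = 2500 * k, materials = 2000 * k,
                           minimum_wage = 668 * k)
  ru <- list(consultations = 2, screenings = 1, medication_spend_nrs = 100 * k,
             inpatient_admissions = 1, inpatient_nights = 3, transport_trips = 4,
             food_servings = 30, work_days_lost_inpatient = 2,
             half_days_outpatient = 1, sessions_attended = 6, calls_received = 4,
             minutes_per_call = 3, sms_received = 9)
  ru1 <- ru; ru1$medication_spend_nrs <- 100
  expect_equal(price_resource_use(ru, sched2)$total,
               k * price_resource_use(ru1, sched)$total)
})

test_that("healthcare-perspective switch removes indirect costs only", {
  d <- generate_trial(small_config(seed = 33))
  full <- participant_costs(d, sched, include_indirect = TRUE)
  hc <- participant_costs(d, sched, include_indirect = FALSE)
  expect_true(all(hc$indirect_income_loss == 0))
  expect_equal(hc$total, full$total - full$indirect_income_loss, tolerance = 1e-12)
})

test_that("arm cost table summarises categories and differences", {
  # every participant exactly at the printed category means
  mk <- function(arm, n, means) {
    cb <- cost_breakdown(as.list(setNames(as.list(means), c(
      "consultation", "screening", "medication", "inpatient", "transport",
      "food", "indirect_income_loss", "intervention_phone", "intervention_peer",
      "intervention_training"))))
    cb <- cb[rep(1, n), ]
    cb$arm <- arm
    cb
  }
  int <- mk("intervention", 10, c(4.16, 14.31, 9.35, 2.80, 0.64, 1.62, 12.83, 0.47, 2.53, 14.33))
  ctl <- mk("control", 10, c(3.85, 13.43, 3.68, 1.45, 0.66, 2.06, 9.11, 0, 0, 0))
  tab <- arm_cost_table(rbind(int, ctl), B = 50, seed = 1)
  med <- tab[tab$category == "medication", ]
  expect_equal(med$difference, 9.35 - 3.68)      # 5.67 from printed means
  expect_equal(tab$difference[tab$category == "total"], 63.04 - 34.24,
               tolerance = 1e-10)

  # identical arms: all differences zero, degenerate CIs collapse
  both <- rbind(int, `[<-`(int, "arm", value = "control"))
  tab0 <- arm_cost_table(both, B = 50, seed = 1)
  expect_true(all(tab0$difference == 0))
  expect_true(all(tab0$ci_lower == 0 & tab0$ci_upper == 0))

  expect_error(arm_cost_table(int, B = 10), "per arm")
})

test_that("price schedules survive a CSV round trip", {
  f <- tempfile(fileext = ".csv")
  write_price_schedule(sched, f)
  s2 <- read_price_schedule(f)
  expect_equal(unclass(s2), unclass(sched))
  bad <- data.frame(item = "rocket", price_nrs = 5)
  f2 <- tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(read_price_schedule(f2), "rocket")
})
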