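# Costing: resource use -> per-participant cost breakdown in USD.
#
# Cost taxonomy (per patient over the 6-month trial):
#   direct medical      = consultation + screening + medication + inpatient
#   direct non-medical  = transport + food
#   indirect            = productivity loss (human capital approach)
#   intervention        = phone + peer support + intensive training
#   total               = sum of the four blocks
# All arithmetic is carried out unrounded in USD; prices are supplied in
# Nepali rupees (NRs) and converted at the schedule's exchange rate.
# Rounding to 2 decimals is purely a reporting concern.

COST_CATEGORIES <- c("consultation", "screening", "medication", "inpatient",
                     "transport", "food", "indirect_income_loss",
                     "intervention_phone", "intervention_peer", "intervention_training")

#' Unit-price schedule
#'
#' Prices in Nepali rupees for each resource item, with the minimum daily wage
#' (for human-capital indirect costs) and the NRs/USD exchange rate. Defaults
#' are synthetic placeholders with realistic magnitudes, except the exchange
#' rate (125.20 NRs per USD, 2022 average).
#'
#' @param consultation,screening,bed_day,transport_trip,food_serving Unit
#'   prices in NRs (per visit / test / inpatient night / round trip / serving).
#' @param call_minute,sms Telecom tariffs in NRs.
#' @param trainer_session Cost of delivering one training session to a cluster
#'   (trainer day rate), NRs.
#' @param peer_supporter Payment per peer supporter per trial, NRs (two per
#'   intervention cluster).
#' @param materials Per-cluster materials cost, NRs.
#' @param minimum_wage Daily unskilled-labour minimum wage, NRs (8-h day).
#' @param exchange_rate NRs per USD.
#' @return Object of class `price_schedule`.
#' @export
price_schedule <- function(consultation = 250, screening = 626, bed_day = 1500,
                           transport_trip = 50, food_serving = 30,
                           call_minute = 2, sms = 1,
                           trainer_session = 3000, peer_supporter = 2500,
                           materials = 2000, minimum_wage = 668,
                           exchange_rate = 125.20) {
  prices <- list(consultation = consultation, screening = screening,
                 bed_day = bed_day, transport_trip = transport_trip,
                 food_serving = food_serving, call_minute = call_minute,
                 sms = sms, trainer_session = trainer_session,
                 peer_supporter = peer_supporter, materials = materials,
                 minimum_wage = minimum_wage, exchange_rate = exchange_rate)
  for (nm in names(prices)) assert_positive(prices[[nm]], nm)
  structure(prices, class = "price_schedule")
}

#' Read/write a price schedule as CSV (`item`, `unit`, `price_nrs`)
#' @param path CSV path.
#' @param schedule Schedule to write.
#' @export
read_price_schedule <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item", "price_nrs") %in% names(df))) {
    stop_domain("price CSV needs columns item, price_nrs")
  }
  args <- as.list(setNames(df$price_nrs, df$item))
  known <- names(formals(price_schedule))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop_domain("unknown price items: ", paste(unknown, collapse = ", "))
  do.call(price_schedule, args)
}

#' @rdname read_price_schedule
#' @export
write_price_schedule <- function(schedule, path) {
  units <- c(consultation = "visit", screening = "test", bed_day = "night",
             transport_trip = "round trip", food_serving = "serving",
             call_minute = "minute", sms = "message",
             trainer_session = "session", peer_supporter = "person-trial",
             materials = "cluster", minimum_wage = "day",
             exchange_rate = "NRs per USD")
  df <- data.frame(item = names(schedule),
                   unit = unname(units[names(schedule)]),
                   price_nrs = unlist(schedule, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert Nepali rupees to US dollars
#'
#' @param amount_nrs Non-negative amount(s) in NRs.
#' @param schedule A [price_schedule()] carrying the exchange rate.
#' @return Amount in USD, unrounded.
#' @examples
#' convert_currency(125.20, price_schedule())  # 1
#' @export
convert_currency <- function(amount_nrs, schedule) {
  if (any(amount_nrs < 0, na.rm = TRUE)) stop_domain("amounts in NRs must be non-negative")
  amount_nrs / schedule$exchange_rate
}

#' Indirect (productivity) cost by the human capital approach
#'
#' Inpatient days are valued as full 8-hour workdays at the minimum wage and
#' outpatient visits as 4-hour half-days; no friction-period adjustment.
#'
#' @param work_days_lost_inpatient Days lost to inpatient stays.
#' @param half_days_outpatient Number of outpatient half-days lost.
#' @param schedule A [price_schedule()].
#' @return Indirect cost in USD.
#' @export
indirect_cost <- function(work_days_lost_inpatient, half_days_outpatient, schedule) {
  assert_positive(work_days_lost_inpatient, "work_days_lost_inpatient", strict = FALSE)
  assert_positive(half_days_outpatient, "half_days_outpatient", strict = FALSE)
  nrs <- work_days_lost_inpatient * schedule$minimum_wage +
    half_days_outpatient * 0.5 * schedule$minimum_wage
  convert_currency(nrs, schedule)
}

#' Intervention delivery cost per participant
#'
#' Phone costs accrue per participant from call minutes and messages; peer
#' support (two supporters per cluster) and training sessions (trainer day
#' rate plus materials) are cluster-shared and divided equally per head.
#'
#' @param sessions Training sessions delivered to the cluster.
#' @param calls Calls received by the participant.
#' @param minutes_per_call Average call duration, minutes.
#' @param sms Messages received.
#' @param schedule A [price_schedule()].
#' @param participants_per_cluster Heads sharing the cluster-level costs
#'   (must be >= 1).
#' @return List with `phone`, `peer`, `training`, `total` (USD).
#' @export
intervention_cost <- function(sessions, calls, minutes_per_call, sms, schedule,
                              participants_per_cluster) {
  for (v in list(sessions, calls, minutes_per_call, sms)) {
    assert_positive(v, "intervention delivery counts", strict = FALSE)
  }
  if (any(participants_per_cluster < 1)) stop_domain("participants_per_cluster must be >= 1")
  phone <- convert_currency(calls * minutes_per_call * schedule$call_minute +
                              sms * schedule$sms, schedule)
  # participants with no delivery at all (control arm) cost exactly 0: the
  # cluster-shared components apply only where the intervention was delivered
  delivered <- sessions > 0 | calls > 0 | sms > 0
  peer <- delivered * convert_currency(2 * schedule$peer_supporter, schedule) /
    participants_per_cluster
  training <- delivered * convert_currency(sessions * schedule$trainer_session +
                                             schedule$materials, schedule) /
    participants_per_cluster
  list(phone = phone, peer = peer, training = training,
       total = phone + peer + training)
}

#' Assemble a cost breakdown from its categories
#'
#' Builds the per-participant cost-breakdown data frame from the ten category
#' columns (vectors, one element per participant), adding the block subtotals
#' (direct medical, direct non-medical, intervention) and the grand total.
#' Subtotals and totals are exact sums of their unrounded components.
#'
#' @param categories Named list with the ten category vectors (USD): see
#'   `COST_CATEGORIES` in the package sources.
#' @return A `cost_breakdown` data frame.
#' @export
cost_breakdown <- function(categories) {
  cb <- as.data.frame(categories)
  missing <- setdiff(COST_CATEGORIES, names(cb))
  if (length(missing)) stop_domain("missing cost categories: ", paste(missing, collapse = ", "))
  cb$direct_medical_subtotal <- cb$consultation + cb$screening + cb$medication + cb$inpatient
  cb$direct_non_medical_subtotal <- cb$transport + cb$food
  cb$intervention_total <- cb$intervention_phone + cb$intervention_peer +
    cb$intervention_training
  cb$total <- cb$direct_medical_subtotal + cb$direct_non_medical_subtotal +
    cb$indirect_income_loss + cb$intervention_total
  structure(cb, class = c("cost_breakdown", "data.frame"))
}

#' Price a participant's resource use
#'
#' Multiplies each resource-use quantity by its unit price, converts to USD
#' and assembles the full cost breakdown. Intervention components are computed
#' with [intervention_cost()] from the delivery counts.
#'
#' @param ru A list/one-row data frame of resource-use quantities:
#'   `consultations`, `screenings`, `medication_spend_nrs`,
#'   `inpatient_admissions`, `inpatient_nights`, `transport_trips`,
#'   `food_servings`, `work_days_lost_inpatient`, `half_days_outpatient`,
#'   `sessions_attended`, `calls_received`, `minutes_per_call`,
#'   `sms_received`.
#' @param schedule A [price_schedule()].
#' @param participants_per_cluster Heads sharing cluster-level intervention
#'   costs (only needed when delivery counts are non-zero).
#' @return A one-row `cost_breakdown` data frame (all categories, subtotals,
#'   total; USD).
#' @export
price_resource_use <- function(ru, schedule, participants_per_cluster = 1) {
  needed <- c("consultations", "screenings", "medication_spend_nrs",
              "inpatient_admissions", "inpatient_nights", "transport_trips",
              "food_servings", "work_days_lost_inpatient", "half_days_outpatient",
              "sessions_attended", "calls_received", "minutes_per_call", "sms_received")
  for (nm in needed) {
    if (is.null(ru[[nm]])) stop_domain("resource item without a quantity/price mapping: ", nm)
    assert_positive(ru[[nm]], nm, strict = FALSE)
  }
  if (any(ru$inpatient_admissions == 0 & ru$inpatient_nights > 0)) {
    stop_domain("inpatient_nights must be 0 when inpatient_admissions is 0")
  }
  iv <- intervention_cost(ru$sessions_attended, ru$calls_received,
                          ru$minutes_per_call, ru$sms_received, schedule,
                          participants_per_cluster)
  cost_breakdown(list(
    consultation = convert_currency(ru$consultations * schedule$consultation, schedule),
    screening = convert_currency(ru$screenings * schedule$screening, schedule),
    medication = convert_currency(ru$medication_spend_nrs, schedule),
    inpatient = convert_currency(ru$inpatient_nights * schedule$bed_day, schedule),
    transport = convert_currency(ru$transport_trips * schedule$transport_trip, schedule),
    food = convert_currency(ru$food_servings * schedule$food_serving, schedule),
    indirect_income_loss = indirect_cost(ru$work_days_lost_inpatient,
                                         ru$half_days_outpatient, schedule),
    intervention_phone = iv$phone,
    intervention_peer = iv$peer,
    intervention_training = iv$training
  ))
}

#' Per-participant cost breakdowns for a whole trial dataset
#'
#' Applies [price_resource_use()] vectorised over a participant-level data
#' frame. When the dataset carries pre-computed intervention component costs
#' in USD (columns `int_phone_usd`, `int_peer_usd`, `int_training_usd`, as the
#' synthetic generator emits), those are used directly instead of delivery
#' counts.
#'
#' @param data Participant-level data frame (see [generate_trial()] for the
#'   column dictionary).
#' @param schedule A [price_schedule()].
#' @param include_indirect Keep indirect (productivity) costs in the total?
#'   Setting `FALSE` gives a strict healthcare-system perspective.
#' @return `cost_breakdown` data frame, one row per participant, plus
#'   `participant_id` and `arm` columns.
#' @export
participant_costs <- function(data, schedule, include_indirect = TRUE) {
  n <- nrow(data)
  zero <- numeric(n)
  ru <- list(
    consultations = data$consultations %||% zero,
    screenings = data$screenings %||% zero,
    medication_spend_nrs = data$medication_spend_nrs %||% zero,
    inpatient_admissions = data$inpatient_admissions %||% zero,
    inpatient_nights = data$inpatient_nights %||% zero,
    transport_trips = data$transport_trips %||% zero,
    food_servings = data$food_servings %||% zero,
    work_days_lost_inpatient = data$work_days_lost_inpatient %||% zero,
    half_days_outpatient = data$half_days_outpatient %||% zero,
    sessions_attended = data$sessions_attended %||% zero,
    calls_received = data$calls_received %||% zero,
    minutes_per_call = data$minutes_per_call %||% zero,
    sms_received = data$sms_received %||% zero
  )
  cb <- price_resource_use(ru, schedule, data$participants_per_cluster %||% 1)
  if (!is.null(data$int_phone_usd)) {
    cb <- cost_breakdown(list(
      consultation = cb$consultation, screening = cb$screening,
      medication = cb$medication, inpatient = cb$inpatient,
      transport = cb$transport, food = cb$food,
      indirect_income_loss = cb$indirect_income_loss,
      intervention_phone = data$int_phone_usd,
      intervention_peer = data$int_peer_usd,
      intervention_training = data$int_training_usd
    ))
  }
  if (!include_indirect) {
    cb <- cost_breakdown(list(
      consultation = cb$consultation, screening = cb$screening,
      medication = cb$medication, inpatient = cb$inpatient,
      transport = cb$transport, food = cb$food,
      indirect_income_loss = 0 * cb$indirect_income_loss,
      intervention_phone = cb$intervention_phone,
      intervention_peer = cb$intervention_peer,
      intervention_training = cb$intervention_training
    ))
  }
  cb$participant_id <- data$participant_id %||% seq_len(n)
  cb$arm <- data$arm %||% rep(NA_character_, n)
  cb
}

#' Arm-level cost summary table
#'
#' One row per cost category plus block subtotals and the grand total: mean
#' and SD per arm, and the intervention-minus-control mean difference with a
#' nonparametric bootstrap percentile CI.
#'
#' @param costs A `cost_breakdown` data frame with an `arm` column
#'   ("intervention"/"control").
#' @param B Bootstrap replicates for the difference CIs.
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level.
#' @return Data frame with columns `category`, `mean_intervention`,
#'   `sd_intervention`, `mean_control`, `sd_control`, `difference`,
#'   `ci_lower`, `ci_upper`.
#' @export
arm_cost_table <- function(costs, B = 1000, seed = 1L, conf = 0.95) {
  rows <- c("consultation", "screening", "medication", "inpatient",
            "direct_medical_subtotal", "transport", "food",
            "direct_non_medical_subtotal", "indirect_income_loss",
            "intervention_phone", "intervention_peer", "intervention_training",
            "intervention_total", "total")
  int <- costs[costs$arm == "intervention", , drop = FALSE]
  ctl <- costs[costs$arm == "control", , drop = FALSE]
  if (nrow(int) < 2 || nrow(ctl) < 2) stop_domain("need at least 2 participants per arm")
  set.seed(derive_seed(seed, "arm_cost_table"))
  idx_i <- matrix(sample.int(nrow(int), nrow(int) * B, replace = TRUE), nrow = B)
  idx_c <- matrix(sample.int(nrow(ctl), nrow(ctl) * B, replace = TRUE), nrow = B)
  a <- (1 - conf) / 2
  out <- lapply(rows, function(cat) {
    yi <- int[[cat]]; yc <- ctl[[cat]]
    diffs <- rowMeans(matrix(yi[idx_i], nrow = B)) - rowMeans(matrix(yc[idx_c], nrow = B))
    ci <- percentile_ci(diffs, conf)
    data.frame(category = cat,
               mean_intervention = mean(yi), sd_intervention = sd(yi),
               mean_control = mean(yc), sd_control = sd(yc),
               difference = mean(yi) - mean(yc),
               ci_lower = ci[1], ci_upper = ci[2])
  })
  do.call(rbind, out)
}
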