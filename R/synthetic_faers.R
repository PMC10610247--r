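#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines a generative model for multi-table FAERS-style data with known
#' ground truth. Each case draws its drugs independently by marginal
#' probability; each preferred term (PT) is then drawn with probability
#' whose odds are the PT's baseline odds multiplied by the planted odds
#' multipliers of every drug the case received (effects combine
#' multiplicatively on the odds scale, which gives the model a closed-form
#' ROR oracle, [expected_ror()]). Cases with at least one event become
#' reports; duplicates are emitted as extra report versions of the same
#' case id; therapy windows cover the event date except for a configured
#' fraction emitted deliberately outside it.
#'
#' Default demographic strata follow the large-scale spontaneous-report
#' profile for itching: pruritic cases average 50.3 y / 88.3 kg and 55%
#' female against 53.2 y / 83.4 kg for the rest, and the default baseline
#' makes roughly 1% of reports pruritic.
#'
#' @param n_cases number of base cases to simulate.
#' @param seed integer seed; all randomness flows from this one generator.
#' @param drug_catalog data frame with columns `drug` and `p` (marginal
#'   probability a case receives the drug).
#' @param pt_catalog data frame with columns `pt`, `p0` (baseline event
#'   probability) and `is_pruritus`.
#' @param planted_effects data frame with columns `drug`, `pt`,
#'   `multiplier` (odds multiplier > 0); empty means the null model.
#' @param duplicate_rate probability a case is re-submitted as a second
#'   report version.
#' @param dup_perturb_rate fraction of duplicates whose weight is
#'   perturbed, to exercise keep-latest-version logic.
#' @param missing_date_rate probability a case's event date is blank.
#' @param missing_demo_rate probability each of age and weight is blank.
#' @param out_of_window_rate probability a therapy window is emitted
#'   entirely before the event date.
#' @param indication_overlap_rate probability a case lists a pruritus PT
#'   as an indication (and is therefore excluded downstream).
#' @param gender_split probability a case is female.
#' @param age_dist,weight_dist lists with numeric `pruritus` and `other`
#'   elements `c(mean, sd)`.
#' @param indication_pool non-pruritus indication PTs sampled for drug
#'   indications.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_cases = 5000L,
    seed = 1L,
    drug_catalog = default_drug_catalog(),
    pt_catalog = default_pt_catalog(),
    planted_effects = NULL,
    duplicate_rate = 0.05,
    dup_perturb_rate = 0.5,
    missing_date_rate = 0.05,
    missing_demo_rate = 0.3,
    out_of_window_rate = 0.1,
    indication_overlap_rate = 0.002,
    gender_split = 0.553,
    age_dist = list(pruritus = c(50.30, 20.24), other = c(53.17, 21.09)),
    weight_dist = list(pruritus = c(88.26, 44.93), other = c(83.44, 44.55)),
    indication_pool = c("Hypertension", "Diabetes mellitus", "Depression",
                        "Rheumatoid arthritis")) {
  drug_catalog <- tibble::as_tibble(drug_catalog)
  pt_catalog <- tibble::as_tibble(pt_catalog)
  if (is.null(planted_effects)) {
    planted_effects <- tibble::tibble(drug = character(), pt = character(),
                                      multiplier = numeric())
  }
  planted_effects <- tibble::as_tibble(planted_effects)
  cfg <- structure(
    list(n_cases = as.integer(n_cases), seed = as.integer(seed),
         drug_catalog = drug_catalog, pt_catalog = pt_catalog,
         planted_effects = planted_effects,
         duplicate_rate = duplicate_rate, dup_perturb_rate = dup_perturb_rate,
         missing_date_rate = missing_date_rate,
         missing_demo_rate = missing_demo_rate,
         out_of_window_rate = out_of_window_rate,
         indication_overlap_rate = indication_overlap_rate,
         gender_split = gender_split, age_dist = age_dist,
         weight_dist = weight_dist, indication_pool = indication_pool),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_cases < 1L) stop("n_cases must be positive", call. = FALSE)
  if (nrow(cfg$drug_catalog) == 0L) {
    stop("degenerate config: drug catalog is empty", call. = FALSE)
  }
  if (nrow(cfg$pt_catalog) == 0L) {
    stop("degenerate config: PT catalog is empty", call. = FALSE)
  }
  probs <- c(cfg$drug_catalog$p, cfg$pt_catalog$p0, cfg$duplicate_rate,
             cfg$dup_perturb_rate, cfg$missing_date_rate,
             cfg$missing_demo_rate, cfg$out_of_window_rate,
             cfg$indication_overlap_rate, cfg$gender_split)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$planted_effects$multiplier <= 0)) {
    stop("odds multipliers must be > 0", call. = FALSE)
  }
  bad_d <- setdiff(cfg$planted_effects$drug, cfg$drug_catalog$drug)
  bad_p <- setdiff(cfg$planted_effects$pt, cfg$pt_catalog$pt)
  if (length(bad_d) || length(bad_p)) {
    stop("planted effects reference unknown drug/pt: ",
         paste(c(bad_d, bad_p), collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname synthetic_config
#' @export
default_drug_catalog <- function() {
  tibble::tibble(
    drug = paste0("drug", sprintf("%02d", 1:10)),
    p = c(0.20, 0.15, 0.12, 0.10, 0.08, 0.08, 0.06, 0.05, 0.05, 0.04))
}

#' @rdname synthetic_config
#' @export
default_pt_catalog <- function() {
  tibble::tibble(
    pt = c("Pruritus", "Rash pruritic", "Nausea", "Headache", "Fatigue",
           "Drug ineffective"),
    p0 = c(0.010, 0.003, 0.30, 0.20, 0.15, 0.10),
    is_pruritus = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}

# D x P matrix of log odds multipliers implied by the planted effects
log_multiplier_matrix <- function(cfg) {
  D <- nrow(cfg$drug_catalog); P <- nrow(cfg$pt_catalog)
  M <- matrix(0, D, P, dimnames = list(cfg$drug_catalog$drug, cfg$pt_catalog$pt))
  if (nrow(cfg$planted_effects)) {
    idx <- cbind(match(cfg$planted_effects$drug, cfg$drug_catalog$drug),
                 match(cfg$planted_effects$pt, cfg$pt_catalog$pt))
    M[idx] <- log(cfg$planted_effects$multiplier)
  }
  M
}

#' Generate a synthetic multi-table spontaneous-report dataset
#'
#' Deterministic given `(config, seed)`: two calls with the same config
#' produce byte-identical tables. Returns the five FAERS-layout source
#' tables plus the ground truth needed to verify every downstream stage.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `tables` (named list `demo`, `drug`,
#'   `reac`, `indi`, `ther` of raw FAERS-layout tibbles) and `truth`, a
#'   list holding the planted multiplier grid, per-case
#'   inclusion/exclusion reasons, per-exposure therapy-window status,
#'   duplicate pointers, the event list, and `analysis_rows` — the
#'   analysis set a perfect cleaning pipeline should produce.
#' @export
synth_generate <- function(config) {
  cfg <- validate_synthetic_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_cases
  drugs <- cfg$drug_catalog$drug
  pts <- cfg$pt_catalog$pt
  D <- length(drugs); P <- length(pts)
  case_id <- sprintf("C%07d", seq_len(n))

  # exposures and events
  E <- matrix(stats::runif(n * D), n, D) <
    matrix(cfg$drug_catalog$p, n, D, byrow = TRUE)
  odds0 <- cfg$pt_catalog$p0 / (1 - cfg$pt_catalog$p0)
  logodds <- matrix(log(odds0), n, P, byrow = TRUE) +
    (E * 1) %*% log_multiplier_matrix(cfg)
  Y <- matrix(stats::runif(n * P), n, P) < stats::plogis(logodds)
  pruritus_case <- as.logical(Y[, cfg$pt_catalog$is_pruritus, drop = FALSE] %*%
                                rep(1, sum(cfg$pt_catalog$is_pruritus)) > 0)

  # demographics
  female <- stats::runif(n) < cfg$gender_split
  draw2 <- function(dist) {
    mu <- ifelse(pruritus_case, dist$pruritus[1], dist$other[1])
    sd <- ifelse(pruritus_case, dist$pruritus[2], dist$other[2])
    pmax(round(stats::rnorm(n, mu, sd), 1), 0.1)
  }
  age <- draw2(cfg$age_dist)
  weight <- draw2(cfg$weight_dist)
  age[stats::runif(n) < cfg$missing_demo_rate] <- NA_real_
  weight[stats::runif(n) < cfg$missing_demo_rate] <- NA_real_

  # dates
  event_day <- as.Date("2015-01-01") + sample.int(1826L, n, replace = TRUE) - 1L
  date_missing <- stats::runif(n) < cfg$missing_date_rate
  event_dt <- ifelse(date_missing, "", format(event_day, "%Y%m%d"))

  # per-exposure rows
  exp_idx <- which(E, arr.ind = TRUE)
  exp_idx <- exp_idx[order(exp_idx[, 1L], exp_idx[, 2L]), , drop = FALSE]
  ci <- exp_idx[, 1L]
  drug_name <- drugs[exp_idx[, 2L]]
  drug_seq <- stats::ave(ci, ci, FUN = seq_along)
  n_exp <- length(ci)
  role <- sample(c("PS", "SS", "C", "I"), n_exp, replace = TRUE,
                 prob = c(0.5, 0.2, 0.25, 0.05))
  out_window <- stats::runif(n_exp) < cfg$out_of_window_rate
  lag_start <- sample.int(60L, n_exp, replace = TRUE) - 1L
  lag_end <- sample.int(60L, n_exp, replace = TRUE) - 1L
  start_day <- event_day[ci] - ifelse(out_window, 180L + lag_start, lag_start)
  end_day <- event_day[ci] - ifelse(out_window, 90L, -lag_end)

  # indications: one per exposure; overlap cases flag a pruritus PT
  overlap_case <- stats::runif(n) < cfg$indication_overlap_rate
  indi_pt <- sample(cfg$indication_pool, n_exp, replace = TRUE)
  first_of_case <- !duplicated(ci)
  flag <- overlap_case[ci] & first_of_case
  indi_pt[flag] <- "Pruritus"

  # reactions
  ev_idx <- which(Y, arr.ind = TRUE)
  ev_idx <- ev_idx[order(ev_idx[, 1L], ev_idx[, 2L]), , drop = FALSE]

  # duplicate report versions (appended after the base rows)
  dup <- which(stats::runif(n) < cfg$duplicate_rate)
  perturb <- stats::runif(length(dup)) < cfg$dup_perturb_rate

  demo <- tibble::tibble(
    primaryid = c(case_id, case_id[dup]),
    caseversion = c(rep(1L, n), rep(2L, length(dup))),
    event_dt = c(event_dt, event_dt[dup]),
    sex = c(ifelse(female, "F", "M"), ifelse(female[dup], "F", "M")),
    age = c(age, age[dup]),
    age_cod = "YR",
    wt = c(weight, weight[dup] + ifelse(perturb, 1, 0)),
    wt_cod = "KG")
  drug_tbl <- tibble::tibble(
    primaryid = case_id[ci], drug_seq = drug_seq,
    drugname = drug_name, role_cod = role)
  reac <- tibble::tibble(
    primaryid = case_id[ev_idx[, 1L]], pt = pts[ev_idx[, 2L]])
  indi <- tibble::tibble(
    primaryid = case_id[ci], indi_drug_seq = drug_seq, indi_pt = indi_pt)
  ther <- tibble::tibble(
    primaryid = case_id[ci], dsg_drug_seq = drug_seq,
    start_dt = format(start_day, "%Y%m%d"),
    end_dt = format(end_day, "%Y%m%d"))

  # ground truth
  has_event <- tabulate(ev_idx[, 1L], nbins = n) > 0
  has_drug <- tabulate(ci, nbins = n) > 0
  reason <- dplyr::case_when(
    overlap_case ~ "indication_overlap",
    date_missing ~ "missing_event_date",
    !has_drug ~ "no_drug",
    !has_event ~ "no_event",
    .default = "included")
  exposures <- tibble::tibble(
    case_id = case_id[ci], drug_seq = drug_seq,
    drug_name = normalize_drug_name(drug_name), in_window = !out_window)
  events <- tibble::tibble(case_id = case_id[ev_idx[, 1L]],
                           pt = pts[ev_idx[, 2L]])
  keep_exp <- exposures[exposures$in_window &
                          reason[match(exposures$case_id, case_id)] %in%
                          c("included", "no_event"), c("case_id", "drug_name")]
  analysis_rows <- dplyr::inner_join(keep_exp, events, by = "case_id",
                                     relationship = "many-to-many")
  names(analysis_rows)[names(analysis_rows) == "pt"] <- "event_pt"

  planted <- tibble::as_tibble(expand.grid(drug = drugs, pt = pts,
                                           stringsAsFactors = FALSE))
  planted$multiplier <- exp(log_multiplier_matrix(cfg))[
    cbind(match(planted$drug, drugs), match(planted$pt, pts))]

  truth <- list(
    planted = planted,
    cases = tibble::tibble(case_id = case_id, pruritus = pruritus_case,
                           female = female, age = age, weight = weight,
                           event_date_missing = date_missing,
                           indication_overlap = overlap_case,
                           exclusion_reason = reason),
    exposures = exposures,
    events = events,
    duplicates = tibble::tibble(case_id = case_id[dup],
                                duplicate_version = 2L, of_version = 1L),
    analysis_rows = analysis_rows)

  list(tables = list(demo = demo, drug = drug_tbl, reac = reac,
                     indi = indi, ther = ther),
       truth = truth)
}

#' Asymptotic ROR implied by the generative model
#'
#' Computes, by exact enumeration over all drug-subset outcomes
#' (marginalising co-occurring drugs' multipliers and the requirement that
#' a case report at least one event to enter the analysis set), the
#' population reporting odds ratio for one (drug, PT) pair under the
#' case-drug analysis unit. This is the independent oracle the sampling
#' pipeline is checked against.
#'
#' @param config a [synthetic_config()].
#' @param drug,pt catalog entries to evaluate.
#' @return positive scalar: the model-implied ROR.
#' @export
expected_ror <- function(config, drug, pt) {
  cfg <- validate_synthetic_config(config)
  drugs <- cfg$drug_catalog$drug
  pts <- cfg$pt_catalog$pt
  if (!drug %in% drugs) stop("unknown drug: ", drug, call. = FALSE)
  if (!pt %in% pts) stop("unknown pt: ", pt, call. = FALSE)
  D <- length(drugs)
  if (D > 20L) stop("enumeration oracle supports at most 20 drugs", call. = FALSE)
  xi <- match(drug, drugs)
  ji <- match(pt, pts)
  pd <- cfg$drug_catalog$p
  odds0 <- cfg$pt_catalog$p0 / (1 - cfg$pt_catalog$p0)
  logM <- log_multiplier_matrix(cfg)

  a <- b <- cc <- d <- 0
  for (s in 0:(2^D - 1L)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(D - 1L))) != 0L)
    size <- length(members)
    if (size == 0L) next
    pr <- prod(pd[members], (1 - pd)[-members])
    e <- stats::plogis(log(odds0) + colSums(logM[members, , drop = FALSE]))
    ej <- e[ji]
    q_other <- 1 - prod(1 - e[-ji])     # some non-target event occurs
    x <- as.integer(xi %in% members)
    a  <- a  + pr * x * ej
    b  <- b  + pr * x * (1 - ej) * q_other
    cc <- cc + pr * (size - x) * ej
    d  <- d  + pr * (size - x) * (1 - ej) * q_other
  }
  unname((a * d) / (b * cc))
}
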