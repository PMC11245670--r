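#' Cow-level record cleaning cascade
#'
#' Applies the inclusion cascade for lifetime analyses, in order: cow
#' identifiers must occur on one farm only; cows must have entered the herd
#' on their date of birth; cows must have no evidence of a lactation before
#' herd entry; birth dates must fall inside the study window; cows must have
#' at least one calving; and age at first calving must be realistic
#' (strictly greater than 458 d and strictly less than 1,461 d, the printed
#' day equivalents of the 15-month / 4.5-year bounds).
#'
#' @param cows Cow table: `cow_id`, `farm_id`, `birth_date`, `dam_id`,
#'   `entry_date`, `exit_date`.
#' @param calvings Calving table: `cow_id`, `calving_date`.
#' @param birth_window Length-2 Date vector, inclusive birth-date limits.
#' @return List with `cows` (retained rows) and `report` (a tibble of
#'   `step`, `animals` counts after each step, in cascade order).
#' @export
clean_cows <- function(cows, calvings,
                       birth_window = as.Date(c("2006-01-01", "2015-12-31"))) {
  report <- dplyr::tibble(step = "Animal records", animals = nrow(cows))
  log_step <- function(step, tab) {
    report <<- dplyr::bind_rows(report,
                                dplyr::tibble(step = step, animals = nrow(tab)))
    tab
  }

  farms_per_id <- tapply(cows$farm_id, cows$cow_id,
                         function(f) length(unique(f)))
  cows <- cows[farms_per_id[cows$cow_id] == 1, , drop = FALSE]
  cows <- log_step("Cow identification number occurred on one farm only", cows)

  cows <- log_step("Cows entered herd on their date of birth",
                   cows[cows$entry_date == cows$birth_date, , drop = FALSE])

  first_calving <- tapply(calvings$calving_date, calvings$cow_id, min)
  fc <- as.Date(first_calving[cows$cow_id],
                origin = "1970-01-01")
  prior_lact <- !is.na(fc) & fc < cows$entry_date
  cows <- log_step("Cow had not had a previous lactation on entry to herd",
                   cows[!prior_lact, , drop = FALSE])

  in_window <- cows$birth_date >= birth_window[1] &
    cows$birth_date <= birth_window[2]
  cows <- log_step("Cows born in study window", cows[in_window, , drop = FALSE])

  fc <- as.Date(first_calving[cows$cow_id], origin = "1970-01-01")
  cows <- log_step("Calving records", cows[!is.na(fc), , drop = FALSE])

  fc <- as.Date(first_calving[cows$cow_id], origin = "1970-01-01")
  afc <- as.numeric(fc - cows$birth_date)
  cows <- log_step("Age at first calving >458 d and <1,461 d",
                   cows[afc > 458 & afc < 1461, , drop = FALSE])

  list(cows = dplyr::as_tibble(cows), report = report)
}

#' Milk-record cleaning and lactation assignment
#'
#' Drops records for cows absent from the (already cleaned) cow table;
#' excludes cows (and all their records) whose milk records pre-date their
#' first recorded calving, since such cows were not first-parity at entry;
#' assigns each remaining record to a lactation by bracketing calving dates
#' (half-open: lactation j runs from calving date j up to but excluding
#' calving date j+1, records after the last calving belong to the last
#' lactation) with 0-based DIM; and removes records with implausible daily
#' yield above 100 kg.
#'
#' @param milk Milk table: `cow_id`, `date`, `yield`, plus any composition
#'   columns carried through.
#' @param cows Cleaned cow table.
#' @param calvings Calving table (`cow_id`, `calving_date`).
#' @return List with `milk` (retained records with `lactation` and `dim`
#'   columns), `cows` (cow table minus excluded cows), and `report`
#'   (tibble `step`, `animals`, `records`). The number of records dropped
#'   for unknown cows is attached as attribute `"unknown_cow_records"`.
#' @export
clean_milk <- function(milk, cows, calvings) {
  report <- dplyr::tibble(step = "Milk records",
                          animals = nrow(cows), records = nrow(milk))
  log_step <- function(step, m, c) {
    report <<- dplyr::bind_rows(report, dplyr::tibble(
      step = step, animals = nrow(c), records = nrow(m)))
  }

  known <- milk$cow_id %in% cows$cow_id
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    warning(n_unknown, " milk records for unknown cows dropped")
  milk <- milk[known, , drop = FALSE]

  calvings <- calvings[calvings$cow_id %in% cows$cow_id, , drop = FALSE]
  first_calving <- tapply(calvings$calving_date, calvings$cow_id, min)
  fc <- as.Date(first_calving[milk$cow_id], origin = "1970-01-01")
  pre_calving_cow <- unique(milk$cow_id[milk$date < fc])
  cows <- cows[!cows$cow_id %in% pre_calving_cow, , drop = FALSE]
  milk <- milk[!milk$cow_id %in% pre_calving_cow, , drop = FALSE]

  cd <- split(as.numeric(calvings$calving_date), calvings$cow_id)
  lact <- integer(nrow(milk)); dim0 <- numeric(nrow(milk))
  for (id in unique(milk$cow_id)) {
    rows <- which(milk$cow_id == id)
    dates <- sort(cd[[id]])
    j <- findInterval(as.numeric(milk$date[rows]), dates)
    lact[rows] <- j
    dim0[rows] <- as.numeric(milk$date[rows]) - dates[j]
  }
  milk$lactation <- lact
  milk$dim <- dim0
  log_step("Milk records selected within bracketing calving dates", milk, cows)

  milk <- milk[milk$yield <= 100, , drop = FALSE]
  log_step("Records with yield >100 kg removed", milk, cows)

  out <- list(milk = dplyr::as_tibble(milk), cows = dplyr::as_tibble(cows),
              report = report)
  attr(out, "unknown_cow_records") <- n_unknown
  out
}

#' Herd-years with at least one recorded stressor
#'
#' Event recording is heterogeneous across farms and years; a (farm, year)
#' enters the analysis only when at least one stressor event — mastitis,
#' lameness, or treatment with an antimicrobial or anti-inflammatory product —
#' was recorded in that year on that farm. Vaccines and unmatched records do
#' not count.
#'
#' @param events Categorized event table (`cow_id`, `date`, `category`).
#' @param cows Cow table supplying `farm_id` per `cow_id`.
#' @return Tibble of retained `farm_id`, `year` combinations.
#' @export
filter_recording_herd_years <- function(events, cows) {
  stressors <- c("mastitis", "lameness", "antimicrobial", "anti_inflammatory")
  ev <- events[events$category %in% stressors, , drop = FALSE]
  if (nrow(ev) == 0)
    return(dplyr::tibble(farm_id = character(), year = integer()))
  farm <- cows$farm_id[match(ev$cow_id, cows$cow_id)]
  keep <- !is.na(farm)
  dplyr::distinct(dplyr::tibble(
    farm_id = farm[keep],
    year = as.integer(format(ev$date[keep], "%Y"))))
}

#' Match offspring to the ancestral pregnancy that produced them
#'
#' Generation gap 1 pairs each daughter with the pregnancy of her dam whose
#' calving date equals the daughter's birth date. Generation gap 2 pairs each
#' granddaughter with the pregnancy of her granddam that produced the
#' granddaughter's mother. Pairs produced by the ancestor's first pregnancy
#' are excluded: the ancestor was not lactating during that pregnancy, so
#' production covariates are undefined. Broken pedigree links are skipped and
#' counted in the `"broken_links"` attribute.
#'
#' @param cows Cleaned cow table (needs `cow_id`, `dam_id`, `birth_date`).
#' @param calvings Calving table for the ancestors.
#' @param generation_gap 1 (mother-daughter) or 2 (granddam-granddaughter).
#' @return Tibble `offspring_id`, `ancestor_id`, `pregnancy_index`,
#'   `calving_date` (the ancestor's calving that produced the link).
#' @export
match_pairs <- function(cows, calvings, generation_gap = 1) {
  stopifnot(generation_gap %in% c(1, 2))
  cd <- split(calvings$calving_date, calvings$cow_id)
  cd <- lapply(cd, sort)
  broken <- 0L

  link_one <- function(offspring_id, ancestor_id, link_birth) {
    dates <- cd[[ancestor_id]]
    if (is.null(dates)) { broken <<- broken + 1L; return(NULL) }
    idx <- which(dates == link_birth)
    if (length(idx) != 1) { broken <<- broken + 1L; return(NULL) }
    dplyr::tibble(offspring_id = offspring_id, ancestor_id = ancestor_id,
                  pregnancy_index = idx, calving_date = dates[idx])
  }

  rows <- list()
  for (i in seq_len(nrow(cows))) {
    dam <- cows$dam_id[i]
    if (is.na(dam)) next
    if (generation_gap == 1) {
      rows[[length(rows) + 1]] <-
        link_one(cows$cow_id[i], dam, cows$birth_date[i])
    } else {
      gd <- cows$dam_id[match(dam, cows$cow_id)]
      mother_birth <- cows$birth_date[match(dam, cows$cow_id)]
      if (length(gd) == 0 || is.na(gd) || is.na(mother_birth)) {
        broken <- broken + 1L; next
      }
      rows[[length(rows) + 1]] <-
        link_one(cows$cow_id[i], gd, mother_birth)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- dplyr::tibble(offspring_id = character(), ancestor_id = character(),
                         pregnancy_index = integer(),
                         calving_date = as.Date(character()))
  out <- out[out$pregnancy_index > 1, , drop = FALSE]
  attr(out, "broken_links") <- broken
  out
}
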