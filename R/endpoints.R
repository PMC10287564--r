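# ICD-10 endpoint curation and first-event survival extraction.

ICD10_CHAPTERS <- data.frame(
  chapter = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
              "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII",
              "XIX", "XX"),
  stringsAsFactors = FALSE
)

#' ICD-10 chapter of a three-character code
#'
#' Maps codes A00-Z99 to chapters I-XX by the standard letter/number blocks
#' (e.g. `K74` is chapter XI, `S72` chapter XIX). Codes outside the disease
#' chapters (e.g. the U block) return `NA`.
#'
#' @param code character vector of three-character ICD-10 codes.
#' @return character vector of Roman-numeral chapters.
#' @export
icd10_chapter <- function(code) {
  letter <- substr(code, 1, 1)
  num <- suppressWarnings(as.integer(substr(code, 2, 3)))
  ch <- rep(NA_character_, length(code))
  ch[letter %in% c("A", "B")] <- "I"
  ch[letter == "C" | (letter == "D" & num <= 48)] <- "II"
  ch[letter == "D" & num >= 50] <- "III"
  ch[letter == "E"] <- "IV"
  ch[letter == "F"] <- "V"
  ch[letter == "G"] <- "VI"
  ch[letter == "H" & num <= 59] <- "VII"
  ch[letter == "H" & num >= 60] <- "VIII"
  ch[letter == "I"] <- "IX"
  ch[letter == "J"] <- "X"
  ch[letter == "K"] <- "XI"
  ch[letter == "L"] <- "XII"
  ch[letter == "M"] <- "XIII"
  ch[letter == "N"] <- "XIV"
  ch[letter == "O"] <- "XV"
  ch[letter == "P"] <- "XVI"
  ch[letter == "Q"] <- "XVII"
  ch[letter == "R"] <- "XVIII"
  ch[letter %in% c("S", "T")] <- "XIX"
  ch[letter %in% c("V", "W", "X", "Y")] <- "XX"
  ch[is.na(num)] <- NA_character_
  ch
}

#' Load the shipped endpoint definition catalog
#'
#' Reads an editable CSV of named endpoints (id, label, semicolon-separated
#' three-character code sets, chapter, WHO-alcohol-related flag). The
#' shipped file covers the named alcohol-related and newly alcohol-associated
#' endpoints plus common control conditions; unlisted codes fall into
#' chapter-wise less-common pools during curation.
#'
#' @param path CSV path; defaults to the catalog shipped with the package.
#' @return data.frame with `id`, `label`, `codes`, `chapter`, `who_flag`.
#' @export
load_endpoint_catalog <- function(path = system.file("extdata",
                                                     "endpoints.csv",
                                                     package = "phewasmr")) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label", "codes", "chapter", "who_flag") %in%
                  names(cat)))
  cat$who_flag <- as.logical(cat$who_flag)
  cat
}

catalog_code_list <- function(catalog) {
  strsplit(catalog$codes, ";", fixed = TRUE)
}

#' Endpoint definitions of a simulation configuration
#'
#' Turns the endpoint-effect table of a [sim_config()] into a catalog
#' suitable for [curate_endpoint_catalog()] and [run_phenome_scan()].
#'
#' @param config a [sim_config()].
#' @return data.frame `id`, `label`, `codes`, `chapter`, `who_flag`.
#' @export
catalog_from_config <- function(config) {
  config$endpoints[, c("id", "label", "codes", "chapter", "who_flag")]
}

#' Curate the endpoint catalog against observed events
#'
#' Endpoints with at least `min_cases` first events among current drinkers
#' (distinct participants, within the age window) are retained individually;
#' all remaining event codes are pooled into one "less-common" endpoint per
#' ICD-10 chapter. Chapters XVI (perinatal) and XVII (congenital) are always
#' excluded, and chapter XV (pregnancy) is excluded for men. Event codes
#' that map to no ICD-10 chapter are rejected and reported in the
#' `rejected_codes` attribute.
#'
#' @param events data.frame `id`, `code`, `age`.
#' @param exposure exposure table from [derive_exposure()].
#' @param sex `"M"` or `"F"`: curation is sex specific.
#' @param catalog endpoint definitions ([load_endpoint_catalog()]).
#' @param min_cases minimum current-drinker first-event count (default 80).
#' @param window age-at-risk window used when counting cases.
#' @return data.frame catalog with `n_cases_current` and `type`
#'   (`"individual"`/`"less_common"`) columns; only retained rows.
#' @export
curate_endpoint_catalog <- function(events, exposure, sex,
                                    catalog = load_endpoint_catalog(),
                                    min_cases = 80, window = c(35, 85)) {
  excluded_ch <- if (sex == "M") c("XV", "XVI", "XVII") else c("XVI", "XVII")
  chap <- icd10_chapter(events$code)
  rejected <- unique(events$code[is.na(chap)])
  ok <- !is.na(chap) & !chap %in% excluded_ch
  ev <- events[ok, , drop = FALSE]
  ev$chapter <- chap[ok]

  keep_ids <- exposure$id[exposure$sex == sex]
  cur_ids <- exposure$id[exposure$sex == sex & !is.na(exposure$status) &
                           exposure$status == "current"]
  ev <- ev[ev$id %in% keep_ids, , drop = FALSE]
  inwin <- ev$age >= window[1] & ev$age < window[2]

  code_list <- catalog_code_list(catalog)
  n_cases <- integer(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    sel <- inwin & ev$code %in% code_list[[i]] & ev$id %in% cur_ids
    n_cases[i] <- length(unique(ev$id[sel]))
  }
  cat_chapters <- catalog$chapter
  retain <- n_cases >= min_cases & !cat_chapters %in% excluded_ch
  out <- catalog[retain, , drop = FALSE]
  out$n_cases_current <- n_cases[retain]
  out$type <- rep("individual", nrow(out))

  # pool every code not claimed by a retained endpoint into its chapter's
  # less-common endpoint
  claimed <- unlist(code_list[retain])
  residual <- ev[!ev$code %in% claimed, , drop = FALSE]
  if (nrow(residual) > 0) {
    for (ch in sort(unique(residual$chapter))) {
      codes <- sort(unique(residual$code[residual$chapter == ch]))
      sel <- inwin & ev$code %in% codes & ev$id %in% cur_ids
      out <- rbind(out, data.frame(
        id = paste0("less_common_", ch),
        label = paste("Less-common conditions, chapter", ch),
        codes = paste(codes, collapse = ";"),
        chapter = ch, who_flag = FALSE,
        n_cases_current = length(unique(ev$id[sel])),
        type = "less_common", stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  attr(out, "rejected_codes") <- rejected
  out
}

#' Extract first-event survival data for an endpoint
#'
#' Per participant, follow-up runs from `max(baseline age, window start)` to
#' the earliest of the first event of the endpoint, death, administrative
#' censoring and the window end (age 85 by default). Events before the
#' window start are discarded; death before any event censors at death
#' (cause-specific hazard convention).
#'
#' @param events events data.frame (`id`, `code`, `age`).
#' @param codes character vector of three-character codes defining the
#'   endpoint.
#' @param participants participants data.frame with `id`, `age_baseline`,
#'   `end_age` (and `death_age` for the censoring reason).
#' @param window age-at-risk window, default `c(35, 85)`.
#' @return data.frame `id`, `entry`, `exit`, `event`, `censor_reason`
#'   (participants with no person-time inside the window are dropped).
#' @export
extract_first_events <- function(events, codes, participants,
                                 window = c(35, 85)) {
  p <- participants
  ev <- events[events$code %in% codes, , drop = FALSE]
  if (nrow(ev) > 0 &&
      any(ev$age > p$end_age[match(ev$id, p$id)] + 1e-9, na.rm = TRUE))
    stop("event age outside participant follow-up")
  ev <- ev[ev$id %in% p$id, , drop = FALSE]
  entry <- pmax(p$age_baseline, window[1])
  exit0 <- pmin(p$end_age, window[2])
  first <- rep(NA_real_, nrow(p))
  ev <- ev[ev$age >= window[1], , drop = FALSE]
  if (nrow(ev) > 0) {
    agg <- tapply(ev$age, ev$id, min)
    idx <- match(as.integer(names(agg)), p$id)
    first[idx] <- as.numeric(agg)
  }
  event <- !is.na(first) & first < exit0 & first > entry
  exit <- ifelse(event, first, exit0)
  reason <- rep("study-end", nrow(p))
  reason[!is.na(p$death_age) & !event & p$death_age <= exit0] <- "death"
  reason[exit0 >= window[2] & !event &
           (is.na(p$death_age) | p$death_age > window[2])] <- "age-85"
  reason[event] <- "event"
  out <- data.frame(id = p$id, entry = entry, exit = exit,
                    event = as.integer(event), censor_reason = reason,
                    stringsAsFactors = FALSE)
  out[out$entry < out$exit, , drop = FALSE]
}

#' Aggregate endpoint survival data
#'
#' Builds the survival dataset of an aggregate endpoint (e.g. "all
#' WHO alcohol-related diseases") from the union of its members' code sets:
#' each participant's earliest member event counts as the aggregate event.
#'
#' @param catalog curated catalog.
#' @param member_ids endpoint ids forming the aggregate (non-empty).
#' @param events,participants,window as in [extract_first_events()].
#' @return survival data.frame as from [extract_first_events()].
#' @export
build_aggregate_endpoint <- function(catalog, member_ids, events,
                                     participants, window = c(35, 85)) {
  if (length(member_ids) == 0) stop("aggregate needs at least one member")
  rows <- catalog$id %in% member_ids
  if (!any(rows)) stop("no catalog rows match the member ids")
  codes <- unique(unlist(catalog_code_list(catalog[rows, , drop = FALSE])))
  extract_first_events(events, codes, participants, window)
}
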