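# Serialisation of trial datasets: one long CSV (patient, time point,
# field, value) plus a JSON sidecar holding the generator configuration.

#' Write / read a trial dataset
#'
#' `write_dataset()` writes `<path>` as a long CSV with columns
#' `id, time, field, value` (empty value = missing) and a JSON sidecar
#' `<path>.json` carrying the configuration. `read_dataset()` reverses
#' it, validating the schema: questionnaire item levels must lie in
#' their instrument range and resource counts must be non-negative;
#' violations are reported with the offending row and column.
#'
#' @param dataset a `trial_dataset`.
#' @param path CSV file path.
#' @return `read_dataset` returns a `trial_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  long <- dataset_to_long(dataset)
  utils::write.csv(long, path, row.names = FALSE, na = "")
  cfg <- unclass(dataset$config)
  cfg$missingness_coefficients <- as.list(cfg$missingness_coefficients)
  jsonlite::write_json(cfg, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

dataset_to_long <- function(ds) {
  p <- ds$patients
  num <- function(x) ifelse(is.na(x), "", format(x, scientific = FALSE,
                                                 trim = TRUE))
  pat <- data.frame(
    id = rep(p$id, 7L), time = "",
    field = rep(c("arm", "centre", "age", "pfmt", "ui_type",
                  "surgery_received", "surgery_day"), each = nrow(p)),
    value = c(p$arm, num(p$centre), num(p$age), num(p$pfmt), p$ui_type,
              num(as.integer(p$surgery_received)), num(p$surgery_day)),
    stringsAsFactors = FALSE)
  iv <- ds$intervention
  iv_fields <- setdiff(names(iv), "id")
  ivl <- data.frame(
    id = rep(iv$id, length(iv_fields)), time = "surgery",
    field = rep(paste0("int_", iv_fields), each = nrow(iv)),
    value = unlist(lapply(iv_fields, function(f) {
      v <- iv[[f]]
      if (is.logical(v)) num(as.integer(v))
      else if (is.numeric(v)) num(v) else as.character(v)
    }), use.names = FALSE),
    stringsAsFactors = FALSE)
  e <- ds$eq5d
  eql <- data.frame(
    id = rep(e$id, length(EQ5D_DIMENSIONS)), time = rep(e$time, 5L),
    field = rep(paste0("eq5d_", EQ5D_DIMENSIONS), each = nrow(e)),
    value = unlist(lapply(EQ5D_DIMENSIONS, function(d) num(e[[d]])),
                   use.names = FALSE),
    stringsAsFactors = FALSE)
  q <- ds$iciq
  iteml <- paste0("item", 1:8)
  icl <- data.frame(
    id = rep(q$id, 8L), time = rep(q$time, 8L),
    field = rep(paste0("iciq_", iteml), each = nrow(q)),
    value = unlist(lapply(iteml, function(d) num(q[[d]])), use.names = FALSE),
    stringsAsFactors = FALSE)
  r <- ds$resource_use
  rul <- data.frame(id = r$id, time = r$period,
                    field = paste0("ru_", r$item), value = num(r$count),
                    stringsAsFactors = FALSE)
  rbind(pat, ivl, eql, icl, rul)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  check_that(all(c("id", "time", "field", "value") %in% names(long)),
             "dataset file", "needs columns id, time, field, value")
  cfg_path <- paste0(path, ".json")
  config <- if (file.exists(cfg_path)) {
    cj <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    trial_config(
      n_per_arm = cj$n_per_arm, n_centres = cj$n_centres,
      true_cost_effect = cj$true_cost_effect,
      true_utility_effect = cj$true_utility_effect,
      baseline_utility_mean = cj$baseline_utility_mean,
      baseline_utility_sd = cj$baseline_utility_sd,
      surgery_delay_meanlog = cj$surgery_delay_meanlog,
      surgery_delay_sdlog = cj$surgery_delay_sdlog,
      p_no_surgery = cj$p_no_surgery, cost_shape = cj$cost_shape,
      missingness_coefficients = unlist(cj$missingness_coefficients),
      target_missing_fraction = cj$target_missing_fraction,
      seed = cj$seed)
  } else trial_config()

  long$value[long$value == ""] <- NA_character_
  wide <- function(rows, fields, ids) {
    out <- lapply(fields, function(f) {
      v <- rows[rows$field == f, c("id", "value")]
      v$value[match(ids, v$id)]
    })
    names(out) <- fields
    out
  }

  prow <- long[long$time == "", ]
  ids <- unique(prow$id)
  pw <- wide(prow, c("arm", "centre", "age", "pfmt", "ui_type",
                     "surgery_received", "surgery_day"), ids)
  patients <- data.frame(
    id = ids, arm = pw$arm, centre = as.integer(pw$centre),
    age = as.numeric(pw$age), pfmt = as.integer(pw$pfmt),
    ui_type = pw$ui_type,
    surgery_received = as.integer(pw$surgery_received) == 1L,
    surgery_day = as.numeric(pw$surgery_day), stringsAsFactors = FALSE)

  ivrow <- long[long$time == "surgery", ]
  iv_ids <- unique(ivrow$id)
  ivf <- c("device_type", "device_count", "anaesthesia",
           "anaesthetist_present", "theatre_minutes", "recovery_minutes",
           "los_days", "n_nurse_band5", "n_nurse_band4", "catheters",
           "return_theatre", "consumables_cost")
  ivw <- wide(ivrow, paste0("int_", ivf), iv_ids)
  intervention <- data.frame(
    id = iv_ids, device_type = ivw$int_device_type,
    device_count = as.integer(ivw$int_device_count),
    anaesthesia = ivw$int_anaesthesia,
    anaesthetist_present = as.integer(ivw$int_anaesthetist_present) == 1L,
    theatre_minutes = as.numeric(ivw$int_theatre_minutes),
    recovery_minutes = as.numeric(ivw$int_recovery_minutes),
    los_days = as.integer(ivw$int_los_days),
    n_nurse_band5 = as.integer(ivw$int_n_nurse_band5),
    n_nurse_band4 = as.integer(ivw$int_n_nurse_band4),
    catheters = as.integer(ivw$int_catheters),
    return_theatre = as.integer(ivw$int_return_theatre) == 1L,
    consumables_cost = as.numeric(ivw$int_consumables_cost),
    stringsAsFactors = FALSE)

  read_items <- function(prefix, items, times, max_level) {
    rows <- long[startsWith(long$field, prefix) & long$time %in% times, ]
    if (nrow(rows) == 0L) return(NULL)
    key <- paste(rows$id, rows$time)
    ukey <- unique(key)
    out <- data.frame(id = sub(" .*", "", ukey),
                      time = sub(".* ", "", ukey), stringsAsFactors = FALSE)
    for (it in items) {
      f <- paste0(prefix, it)
      v <- rows[rows$field == f, ]
      lev <- suppressWarnings(as.integer(v$value[match(ukey,
                                                 paste(v$id, v$time))]))
      bad <- which(!is.na(lev) & (lev < 1L | lev > max_level))
      if (length(bad))
        fail_validation(f, sprintf(
          "item level %d out of range 1..%d (patient %s, time %s)",
          lev[bad[1]], max_level, out$id[bad[1]], out$time[bad[1]]))
      out[[it]] <- lev
    }
    out[order(out$id, match(out$time, times)), ]
  }

  eq5d <- read_items("eq5d_", EQ5D_DIMENSIONS, EQ5D_TIMES, 3L)
  iciq <- read_items("iciq_", paste0("item", 1:8), ICIQ_TIMES, 4L)
  rownames(eq5d) <- NULL
  rownames(iciq) <- NULL

  rurow <- long[startsWith(long$field, "ru_"), ]
  resource_use <- data.frame(
    id = rurow$id, period = rurow$time,
    item = sub("^ru_", "", rurow$field),
    count = suppressWarnings(as.integer(rurow$value)),
    stringsAsFactors = FALSE)
  bad <- which(!is.na(resource_use$count) & resource_use$count < 0)
  if (length(bad))
    fail_validation("resource_use", sprintf(
      "negative count %d (patient %s, period %s, item %s)",
      resource_use$count[bad[1]], resource_use$id[bad[1]],
      resource_use$period[bad[1]], resource_use$item[bad[1]]))
  resource_use <- resource_use[order(resource_use$id,
                                     match(resource_use$period, COST_PERIODS),
                                     resource_use$item), ]
  rownames(resource_use) <- NULL

  structure(list(patients = patients, intervention = intervention,
                 eq5d = eq5d, iciq = iciq, resource_use = resource_use,
                 config = config),
            class = "trial_dataset")
}
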