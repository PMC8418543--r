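# Staggered-batch scheduling: the first batch occupies the full recipe
# batch time; every subsequent batch starts one recipe cycle time after the
# previous one (the convention of batch-process simulators).

#' Batches per year under staggered scheduling
#'
#' `floor((AOT - batch_time) / cycle_time) + 1`.  With the base-case recipe
#' times (7,200 h/yr; 161.7/46.67 h single stage, 193.1/85.75 h
#' semicontinuous) this gives 151 and 82 batches per year.
#'
#' @param aot annual operating time (h)
#' @param batch_time recipe batch time (h)
#' @param cycle_time recipe cycle time (h)
#' @return integer batch count
#' @examples
#' batches_per_year(7200, 161.7, 46.67)  # 151
#' batches_per_year(7200, 193.1, 85.75)  # 82
#' @export
batches_per_year <- function(aot, batch_time, cycle_time) {
  if (cycle_time <= 0) stop("cycle time must be positive", call. = FALSE)
  if (aot < batch_time)
    stop("annual operating time is below one batch time", call. = FALSE)
  as.integer(floor((aot - batch_time) / cycle_time) + 1)
}

#' Annual production from a batch result
#'
#' @param b a `bmn_batch`
#' @param n batches per year (>= 1)
#' @return list with `recovered_kg` (product basis) and `produced_kg`
#'   (fermenter basis)
#' @export
annual_production <- function(b, n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  list(recovered_kg = n * b$magnetite_recovered_kg,
       produced_kg = n * b$magnetite_produced_kg)
}

#' Annual schedule for a scenario
#'
#' @param scenario a `bmn_scenario`
#' @param batch a `bmn_batch` from [simulate_batch()]
#' @return a `bmn_schedule`: batch count, annual product (recovered and
#'   produced basis) and labor hours by section
#' @export
build_schedule <- function(scenario, batch) {
  sp <- scenario$schedule
  n <- batches_per_year(sp$annual_operating_time_h, sp$batch_time_h,
                        sp$cycle_time_h)
  ann <- annual_production(batch, n)
  lh <- unlist(sp$labor_hours_per_batch)
  structure(list(
    batches_per_year = n,
    batch_time_h = sp$batch_time_h,
    cycle_time_h = sp$cycle_time_h,
    annual_operating_time_h = sp$annual_operating_time_h,
    annual_product_kg = ann$recovered_kg,
    annual_produced_kg = ann$produced_kg,
    labor_hours_per_batch = lh,
    annual_labor_hours = n * sum(lh),
    annual_labor_hours_by_section = n * lh), class = "bmn_schedule")
}

#' @export
print.bmn_schedule <- function(x, ...) {
  cat("<bmn_schedule>", x$batches_per_year, "batches/yr,",
      sprintf("%.1f kg/yr recovered product,", x$annual_product_kg),
      sprintf("%.0f labor h/yr\n", x$annual_labor_hours))
  invisible(x)
}
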