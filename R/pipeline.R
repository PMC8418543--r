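# End-to-end run with report files and a run manifest.

summary_table <- function(res) {
  sch <- res$schedule; cap <- res$capital; op <- res$operating
  ec <- res$economics
  data.frame(
    quantity = c("annual_operating_time_h", "batch_time_h", "cycle_time_h",
                 "batches_per_year", "annual_product_kg",
                 "capital_investment_musd", "total_plant_cost_musd",
                 "equipment_cost_musd", "operating_cost_musd_yr",
                 "unit_production_cost_usd_kg", "msp_usd_kg"),
    value = c(sch$annual_operating_time_h, sch$batch_time_h,
              sch$cycle_time_h, sch$batches_per_year, sch$annual_product_kg,
              cap$total_investment_usd / 1e6, cap$total_plant_cost_usd / 1e6,
              cap$equipment_total_usd / 1e6, op$total_usd_per_yr / 1e6,
              ec$unit_production_cost_usd_kg, ec$msp_usd_kg),
    stringsAsFactors = FALSE)
}

breakdown_table <- function(op) {
  rbind(
    data.frame(group = "direct", category = names(op$direct),
               cost_usd_yr = unname(op$direct), stringsAsFactors = FALSE),
    data.frame(group = "indirect", category = names(op$indirect),
               cost_usd_yr = unname(op$indirect), stringsAsFactors = FALSE),
    data.frame(group = "section", category = names(op$by_section),
               cost_usd_yr = unname(op$by_section), stringsAsFactors = FALSE))
}

#' Run the full analysis and write reports
#'
#' Executes the whole pipeline on a scenario and writes, under `out_dir`:
#' `summary.csv` (schedule/capital/operating/unit-cost/MSP summary),
#' `cost_breakdown.csv`, `materials.csv` (annual priced demand),
#' `stream_table.csv` (downstream magnetite streams), `equipment.csv`,
#' `payback_curve.csv`, `provenance.csv`, `scenario.yaml` (the scenario as
#' run), `summary.json` and `manifest.json`.  Validation warnings are
#' reported via `warning()`; validation errors abort before anything is
#' written.
#'
#' @param scenario a `bmn_scenario`, fixture name, or scenario file path
#' @param out_dir output directory (created if needed)
#' @param seed optional integer recorded in the manifest (the deterministic
#'   pipeline itself draws no random numbers)
#' @return the run manifest (list), invisibly; `$files` lists every output
#' @export
run_full_analysis <- function(scenario, out_dir, seed = NULL) {
  if (is.character(scenario) && length(scenario) == 1L)
    scenario <- if (file.exists(scenario)) load_scenario(scenario)
      else builtin_fixture(scenario)
  v <- validate_scenario(scenario)
  if (any(v$level == "error")) {
    bad <- v[v$level == "error", ]
    stop("invalid scenario:\n",
         paste0("  - ", bad$path, ": ", bad$message, collapse = "\n"),
         call. = FALSE)
  }
  for (i in which(v$level == "warning"))
    warning(v$path[i], ": ", v$message[i], call. = FALSE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  res <- evaluate_scenario(scenario)

  files <- character()
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
  }
  wcsv <- function(df) function(p) utils::write.csv(df, p, row.names = FALSE)

  ann_mat <- res$operating$materials$table
  put("summary.csv", wcsv(summary_table(res)))
  put("cost_breakdown.csv", wcsv(breakdown_table(res$operating)))
  put("materials.csv", wcsv(ann_mat))
  put("stream_table.csv", wcsv(res$batch$stream_table))
  put("equipment.csv", wcsv(res$capital$equipment))
  put("payback_curve.csv", wcsv(res$economics$payback_curve))
  put("provenance.csv", wcsv(provenance_table(scenario)))
  put("scenario.yaml", function(p) write_scenario(scenario, p))
  put("summary.json", function(p) jsonlite::write_json(list(
    mode = scenario$mode,
    batches_per_year = res$schedule$batches_per_year,
    annual_product_kg = res$schedule$annual_product_kg,
    capital_investment_musd = res$capital$total_investment_usd / 1e6,
    operating_cost_musd_yr = res$operating$total_usd_per_yr / 1e6,
    unit_production_cost_usd_kg =
      res$economics$unit_production_cost_usd_kg,
    msp_usd_kg = res$economics$msp_usd_kg,
    indirect_share = res$operating$indirect_share,
    reference_comparison = reference_comparison(
      res$economics,
      res$operating$materials$total_usd / res$schedule$annual_product_kg)),
    p, auto_unbox = TRUE, digits = NA))

  manifest <- list(
    mode = scenario$mode,
    scenario_hash = unname(tools::md5sum(file.path(out_dir,
                                                   "scenario.yaml"))),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    files = files)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  manifest$files <- c(files, mf)
  invisible(manifest)
}
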