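# On-disk fixture bundles with known ground truth.

.writeTruthCSV <- function(path, x, y, multiplicity = NA_integer_,
                           siteClass = NA_character_) {
  utils::write.csv(data.frame(x_um = x, y_um = y,
                              multiplicity = multiplicity,
                              site_class = siteClass),
                   path, row.names = FALSE)
}

#' Generate a named fixture dataset on disk
#'
#' Writes image stacks (multi-page float TIFF, one per channel),
#' ground-truth tables (CSV) and a JSON manifest listing every file with
#' its md5 checksum. All randomness flows from `seed`, so identical calls
#' produce byte-identical content.
#'
#' Scenarios:
#' \describe{
#'   \item{calibration-ladder}{protein fields at 8 densities spanning
#'     0.01-40 molecules/um^2 on a reduced field, with truth positions.}
#'   \item{u937-like-linear}{replicated binding table generated from the
#'     simple Langmuir truth (K_d = 0.25 nM) at 3 pM vesicles.}
#'   \item{nk-like-cooperative}{binding table from the density-dependent
#'     cooperation truth (K_d1 = 130 nM, K_d2 = 0.09 nM, d = 0.1 um).}
#'   \item{inhibition-dose-response}{dose-response table (IC50 = 1 uM).}
#'   \item{colocalization-slb}{two protein channels plus a vesicle channel
#'     with 5% bleed-through and pair-site-preferring vesicle docking.}
#' }
#'
#' @param scenario scenario name.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
generateFixtureDataset <- function(scenario, dir, seed = 1L) {
  scenarios <- c("calibration-ladder", "nk-like-cooperative",
                 "u937-like-linear", "inhibition-dose-response",
                 "colocalization-slb")
  if (!scenario %in% scenarios)
    stop(sprintf("unknown scenario '%s'; available: %s", scenario,
                 paste(scenarios, collapse = ", ")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  params <- list()
  if (scenario == "calibration-ladder") {
    densities <- c(0.01, 0.03, 0.1, 0.3, 1, 3, 10, 40)
    params$densities <- densities
    for (i in seq_along(densities)) {
      cfg <- simulationConfig(fieldSize = 25.92, frames = 5L,
                              seed = vpiSubSeed(seed, paste0("ladder", i)))
      surf <- simulateProteinSurface(densities[i], cfg)
      stack <- renderImageStack(list(protein = surf), cfg)
      pre <- file.path(dir, sprintf("ladder_%02d", i))
      files <- c(files, writeImageStack(stack, pre))
      tp <- paste0(pre, "_truth.csv")
      .writeTruthCSV(tp, surf@points[, 1], surf@points[, 2],
                     surf@multiplicity)
      files <- c(files, tp)
    }
  } else if (scenario %in% c("u937-like-linear", "nk-like-cooperative",
                             "inhibition-dose-response")) {
    cv <- simulateBindingCurve(scenario, seed = seed)
    tr <- .scenarioTruth(scenario)
    tp <- file.path(dir, "binding_curve.csv")
    utils::write.csv(data.frame(x = cv@x, x_kind = cv@xKind, y = cv@y),
                     tp, row.names = FALSE)
    files <- c(files, tp)
    params$truth <- switch(class(tr$model),
      LangmuirModel = list(model = "langmuir", kd_nM = tr$model@kd,
                           alpha = tr$model@alpha),
      CooperativeModel = list(model = "cooperative", kd1_nM = tr$model@kd1,
                              kd2_nM = tr$model@kd2, d_um = tr$model@d,
                              alpha = tr$model@alpha),
      InhibitionModel = list(model = "ic50", n0 = tr$model@n0,
                             nbg = tr$model@nbg, ic50_uM = tr$model@ic50,
                             h = tr$model@h))
    params$conc_pM <- tr$concPM
  } else if (scenario == "colocalization-slb") {
    beta <- matrix(c(1, 0.05, 0, 0.05, 1, 0, 0, 0, 1), 3, byrow = TRUE)
    cfg <- simulationConfig(fieldSize = 25.92, frames = 5L, crosstalk = beta,
                            seed = vpiSubSeed(seed, "slb"))
    model <- cooperativeModel(kd1 = 130, kd2 = 0.09, d = 0.1, alpha = 1)
    green <- simulateProteinSurface(0.10, cfg)
    redCfg <- cfg; redCfg@seed <- vpiSubSeed(seed, "slb-red")
    red <- simulateProteinSurface(0.07, redCfg)
    vesCfg <- cfg; vesCfg@seed <- vpiSubSeed(seed, "slb-ves")
    ves <- simulateVesicleBinding(green, model, 3000, vesCfg)
    stack <- renderImageStack(list(green = green, red = red, vesicle = ves),
                              cfg)
    pre <- file.path(dir, "slb")
    files <- c(files, writeImageStack(stack, pre))
    for (nm in c("green", "red")) {
      surf <- get(nm)
      tp <- file.path(dir, paste0("slb_", nm, "_truth.csv"))
      .writeTruthCSV(tp, surf@points[, 1], surf@points[, 2],
                     surf@multiplicity)
      files <- c(files, tp)
    }
    tp <- file.path(dir, "slb_vesicle_truth.csv")
    .writeTruthCSV(tp, ves@positions[, 1], ves@positions[, 2],
                   siteClass = ves@siteClass)
    files <- c(files, tp)
    params$crosstalk <- beta
  }
  manifest <- list(scenario = scenario, seed = seed,
                   intensity_scale = 65536,
                   coordinate_convention = "x_um rightward, y_um downward, pixel (0,0) centre at (0,0) um",
                   parameters = params,
                   files = lapply(unname(files), function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
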