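#' Read and validate a study configuration
#'
#' The configuration is one human-editable YAML file:
#'
#' \preformatted{
#' seed: 1
#' fd_config: {blur_sigma: 35, offset: 128, threshold: 128,
#'             morph_radius: 1, morph_iterations: 1,
#'             box_sizes: [2, 3, 4, 6, 8, 12, 16, 32, 64]}
#' subjects:
#'   - id: S01
#'     group: FAP
#'     image: s01.png
#'     spacing_mm: 0.085
#'     rois:
#'       - {label: ROI1, origin_row: 10, origin_col: 10, size: 100}
#'     landmarks: s01_landmarks.json   # optional
#'     mci: {left: C1, right: C2}      # optional
#' }
#'
#' Relative paths are resolved against the config file's directory.
#'
#' @param path path to the YAML config.
#' @return validated config list (class \code{StudyConfig}).
#' @seealso [runStudy()]
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  if (is.null(cfg$subjects) || length(cfg$subjects) == 0L)
    stop("config error: no subjects defined")
  ids <- vapply(cfg$subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids))
    stop("config error: duplicated subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  groups <- vapply(cfg$subjects, function(s) as.character(s$group), character(1))
  if (length(unique(groups)) < 1L) stop("config error: missing group labels")
  for (i in seq_along(cfg$subjects)) {
    s <- cfg$subjects[[i]]
    if (is.null(s$image)) stop("config error: subject ", ids[i], " has no image")
    cfg$subjects[[i]]$image <- resolve(s$image)
    if (!file.exists(cfg$subjects[[i]]$image))
      stop("config error: image for subject ", ids[i],
           " does not exist: ", cfg$subjects[[i]]$image)
    if (!is.null(s$landmarks)) {
      cfg$subjects[[i]]$landmarks <- resolve(s$landmarks)
      if (!file.exists(cfg$subjects[[i]]$landmarks))
        stop("config error: landmark file for subject ", ids[i],
             " does not exist: ", cfg$subjects[[i]]$landmarks)
    }
  }
  fc <- cfg$fd_config
  cfg$fdConfig <- fdConfig(
    blurSigma = fc$blur_sigma %||% 35,
    offset = fc$offset %||% 128,
    threshold = fc$threshold %||% 128,
    morphRadius = fc$morph_radius %||% 1L,
    morphIterations = fc$morph_iterations %||% 1L,
    boxSizes = unlist(fc$box_sizes) %||% c(2, 3, 4, 6, 8, 12, 16, 32, 64))
  class(cfg) <- "StudyConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a landmark annotation file
#'
#' JSON with per-side foramen and border traces:
#' \preformatted{
#' {"spacing_mm": 0.1,
#'  "sides": {"right": {"foramen": [r, c],
#'                      "inferior_border": [[r, c], ...],
#'                      "endosteal_margin": [[r, c], ...]},
#'            "left": {...}}}
#' }
#'
#' @param path JSON file path.
#' @param spacingMM spacing override; defaults to the file's
#'   \code{spacing_mm}.
#' @return named list of [CorticalLandmarks-class], one per annotated
#'   side.
#' @export
readLandmarks <- function(path, spacingMM = NULL) {
  if (!file.exists(path)) stop("landmark file does not exist: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- spacingMM %||% j$spacing_mm
  if (is.null(sp)) stop("landmark file ", path, " does not state spacing_mm")
  out <- lapply(names(j$sides), function(sd) {
    s <- j$sides[[sd]]
    corticalLandmarks(foramenCenter = unlist(s$foramen),
                      inferiorBorder = .asPointMatrix(s$inferior_border),
                      endostealMargin = .asPointMatrix(s$endosteal_margin),
                      side = sd, spacing = sp)
  })
  names(out) <- names(j$sides)
  out
}

## a simple 31-bit polynomial content hash, so run manifests can
## fingerprint configs without further dependencies
.contentHash <- function(x) {
  bytes <- utf8ToInt(as.character(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a full radiomorphometric study
#'
#' For every subject: the fractal dimension of each configured ROI, the
#' cortical width per annotated side, and the MCI grade record.  Per
#' variable the two groups are then summarized and compared with the
#' pooled Student t test; MCI counts get a chi-square test of
#' independence; post hoc power (rms-SD effect size, noncentral t) is
#' reported for each significant variable.  Subjects failing one stage
#' are excluded from that variable only, with the exclusion recorded.
#'
#' @param config a \code{StudyConfig} from [readStudyConfig()], or a
#'   path to one.
#' @param outputDir if non-NULL, write per-subject and per-table CSVs
#'   plus a JSON run manifest there.
#' @param powerAll report power for every variable, not only the
#'   significant ones.
#' @param alpha significance level for the power gate (default 0.05).
#' @return list of class \code{StudyTables}: \code{fdTable},
#'   \code{mciTable} (with \code{chi2}, \code{p}), \code{mcwTable},
#'   \code{powerTable}, \code{subjects} (per-subject long table),
#'   \code{errors} (excluded subject/variable pairs).
#' @export
runStudy <- function(config, outputDir = NULL, powerAll = FALSE, alpha = 0.05) {
  if (is.character(config)) config <- readStudyConfig(config)
  stopifnot(inherits(config, "StudyConfig"))
  errors <- data.frame(subject = character(0), variable = character(0),
                       message = character(0))
  rows <- list()
  mciRows <- list()
  for (s in config$subjects) {
    img <- tryCatch(loadGrayImage(s$image, spacingMM = s$spacing_mm %||% NA_real_),
                    error = function(e) e)
    if (inherits(img, "error")) {
      errors <- rbind(errors, data.frame(subject = s$id, variable = "(image)",
                                         message = conditionMessage(img)))
      next
    }
    for (r in s$rois %||% list()) {
      roi <- roiSpec(r$label, r$origin_row, r$origin_col, r$size %||% 100L)
      res <- tryCatch(computeFD(img, roi, config$fdConfig), error = function(e) e)
      if (inherits(res, "error")) {
        errors <- rbind(errors, data.frame(subject = s$id, variable = roi@label,
                                           message = conditionMessage(res)))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s$id, group = s$group,
          variable = paste0("FD-", roi@label), value = fdValue(res))
      }
    }
    if (!is.null(s$landmarks)) {
      lmks <- tryCatch(readLandmarks(s$landmarks, spacingMM = s$spacing_mm),
                       error = function(e) e)
      if (inherits(lmks, "error")) {
        errors <- rbind(errors, data.frame(subject = s$id, variable = "MCW",
                                           message = conditionMessage(lmks)))
      } else {
        for (lmk in lmks) {
          res <- tryCatch(measureMCW(lmk), error = function(e) e)
          vn <- paste0("MCW-", lmk@side)
          if (inherits(res, "error")) {
            errors <- rbind(errors, data.frame(subject = s$id, variable = vn,
                                               message = conditionMessage(res)))
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              subject = s$id, group = s$group, variable = vn,
              value = widthMM(res))
          }
        }
      }
    }
    for (sd_ in names(s$mci %||% list())) {
      mciRows[[length(mciRows) + 1L]] <- data.frame(
        subject = s$id, group = s$group, side = sd_,
        grade = as.character(s$mci[[sd_]]))
    }
  }
  subjects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), group = character(0),
               variable = character(0), value = numeric(0))

  ## per-variable group summaries + pooled t
  groups <- unique(vapply(config$subjects, function(s) as.character(s$group),
                          character(1)))
  fdVars <- sort(unique(subjects$variable[startsWith(subjects$variable, "FD-")]))
  mcwVars <- sort(unique(subjects$variable[startsWith(subjects$variable, "MCW-")]))
  summarize <- function(vars) {
    out <- lapply(vars, function(v) {
      d <- subjects[subjects$variable == v, ]
      gs <- lapply(groups, function(g) {
        x <- d$value[d$group == g]
        if (length(x) < 2L) return(NULL)
        groupSummary(length(x), mean(x), stats::sd(x))
      })
      if (any(vapply(gs, is.null, logical(1)))) return(NULL)
      tt <- tTestFromSummary(gs[[1]], gs[[2]])
      data.frame(variable = v,
                 n1 = gs[[1]]$n, mean1 = gs[[1]]$mean, sd1 = gs[[1]]$sd,
                 n2 = gs[[2]]$n, mean2 = gs[[2]]$mean, sd2 = gs[[2]]$sd,
                 t = abs(tt$t), df = tt$df, p = tt$p)
    })
    do.call(rbind, out)
  }
  fdTable <- summarize(fdVars)
  mcwTable <- summarize(mcwVars)

  ## MCI contingency + chi-square
  mciTable <- NULL
  if (length(mciRows)) {
    mci <- do.call(rbind, mciRows)
    counts <- tabulateMCI(mci$grade, mci$group)
    chi <- tryCatch(chiSquareIndependence(counts), error = function(e) NULL)
    mciTable <- list(counts = counts,
                     chi2 = if (is.null(chi)) NA_real_ else chi$chi2,
                     df = if (is.null(chi)) NA_real_ else chi$df,
                     p = if (is.null(chi)) NA_real_ else chi$p)
  }

  ## post hoc power for the significant variables (or all, on request)
  powerRows <- list()
  for (tab in list(fdTable, mcwTable)) {
    if (is.null(tab)) next
    for (i in seq_len(nrow(tab))) {
      if (!powerAll && (is.na(tab$p[i]) || tab$p[i] >= alpha)) next
      d <- cohensD(c(tab$n1[i], tab$mean1[i], tab$sd1[i]),
                   c(tab$n2[i], tab$mean2[i], tab$sd2[i]))
      pw <- posthocPowerT(d, tab$n1[i], tab$n2[i], alpha)
      powerRows[[length(powerRows) + 1L]] <- data.frame(
        variable = tab$variable[i], d = d, power = pw$power)
    }
  }
  powerTable <- if (length(powerRows)) do.call(rbind, powerRows) else
    data.frame(variable = character(0), d = numeric(0), power = numeric(0))

  result <- structure(list(fdTable = fdTable, mciTable = mciTable,
                           mcwTable = mcwTable, powerTable = powerTable,
                           subjects = subjects, errors = errors),
                      class = "StudyTables")
  if (nrow(errors) > 0L)
    message(nrow(errors), " subject/variable exclusion(s); see $errors")

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(subjects, file.path(outputDir, "per_subject.csv"),
                     row.names = FALSE)
    if (!is.null(fdTable))
      utils::write.csv(fdTable, file.path(outputDir, "fd_table.csv"),
                       row.names = FALSE)
    if (!is.null(mcwTable))
      utils::write.csv(mcwTable, file.path(outputDir, "mcw_table.csv"),
                       row.names = FALSE)
    if (!is.null(mciTable))
      utils::write.csv(as.data.frame(mciTable$counts),
                       file.path(outputDir, "mci_table.csv"))
    utils::write.csv(powerTable, file.path(outputDir, "power_table.csv"),
                     row.names = FALSE)
    if (nrow(errors) > 0L)
      utils::write.csv(errors, file.path(outputDir, "exclusions.csv"),
                       row.names = FALSE)
    manifest <- list(
      package = "trabeculaR",
      version = as.character(utils::packageVersion("trabeculaR")),
      config_hash = .contentHash(unclass(config)[
        setdiff(names(config), "fdConfig")]),
      n_subjects = length(config$subjects),
      n_exclusions = nrow(errors))
    jsonlite::write_json(manifest, file.path(outputDir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

#' @export
print.StudyTables <- function(x, ...) {
  cat("StudyTables\n")
  if (!is.null(x$fdTable)) {
    cat("\nFractal dimension by ROI:\n"); print(x$fdTable, digits = 4)
  }
  if (!is.null(x$mciTable)) {
    cat("\nMCI counts:\n"); print(x$mciTable$counts)
    cat(sprintf("chi2 = %.3f, df = %d, p = %.3f\n",
                x$mciTable$chi2, x$mciTable$df, x$mciTable$p))
  }
  if (!is.null(x$mcwTable)) {
    cat("\nCortical width (mm):\n"); print(x$mcwTable, digits = 4)
  }
  if (nrow(x$powerTable)) {
    cat("\nPost hoc power:\n"); print(x$powerTable, digits = 4)
  }
  if (nrow(x$errors)) {
    cat("\nExclusions:", nrow(x$errors), "(see $errors)\n")
  }
  invisible(x)
}

#' Rater-reliability report
#'
#' ICC (with confidence interval) and Cronbach's alpha for one or more
#' variables measured repeatedly by the same or different raters.
#'
#' @param ratings a complete subjects x raters numeric matrix, or a
#'   named list of such matrices (one per variable).  If matrices carry
#'   rownames, these must agree across columns-blocks.
#' @param model,unit passed to [iccReliability()].
#' @return data.frame with one row per variable: \code{variable},
#'   \code{icc}, \code{lower}, \code{upper}, \code{alpha}, \code{n},
#'   \code{k}.
#' @export
reliabilityReport <- function(ratings,
                              model = "twoWayRandomAbsolute",
                              unit = "single") {
  if (!is.list(ratings) || is.data.frame(ratings))
    ratings <- list(variable = ratings)
  out <- lapply(names(ratings), function(nm) {
    x <- ratings[[nm]]
    if (is.data.frame(x)) x <- as.matrix(x)
    if (ncol(x) < 2L)
      stop("variable '", nm, "': at least 2 measurement columns are required")
    icc <- iccReliability(x, model = model, unit = unit)
    data.frame(variable = nm, icc = icc$icc, lower = icc$lower,
               upper = icc$upper, alpha = cronbachAlpha(x),
               n = icc$n, k = icc$k)
  })
  do.call(rbind, out)
}
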