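STAGES <- c("egg", "larva", "pupa", "total")
SEXES  <- c("female", "male", "pooled")

#' Construct a development dataset
#'
#' A `dev_dataset` is an ordered table of stage-resolved development
#' observations at constant temperatures. Each row is one
#' (stage, sex, temperature) cell: the mean development time in days, its
#' standard error, and the cohort size. Complete developmental failure at a
#' temperature (e.g. no egg hatch) is encoded as `developed = FALSE` with a
#' missing duration.
#'
#' @param stage character vector, each one of `"egg"`, `"larva"`, `"pupa"`,
#'   `"total"`.
#' @param sex character vector, each one of `"female"`, `"male"`, `"pooled"`.
#' @param temperature_C numeric, rearing temperature in degrees Celsius.
#' @param mean_days numeric, mean development time in days (> 0); `NA` for
#'   failure rows.
#' @param se_days numeric, standard error of the mean in days (>= 0, optional:
#'   `NA` allowed).
#' @param n integer cohort size (>= 0; 0 only allowed for failure rows).
#' @param developed logical; `FALSE` marks complete failure to develop.
#' @param label free-text dataset label.
#' @return A data frame of class `dev_dataset` with the seven columns above.
#' @examples
#' dev_dataset(stage = "egg", sex = "female", temperature_C = 25,
#'             mean_days = 3.3, se_days = 0.0, n = 115)
#' @export
dev_dataset <- function(stage, sex, temperature_C, mean_days,
                        se_days = NA_real_, n = NA_integer_,
                        developed = TRUE, label = "") {
  df <- data.frame(
    stage = as.character(stage),
    sex = as.character(sex),
    temperature_C = as.numeric(temperature_C),
    mean_days = as.numeric(mean_days),
    se_days = as.numeric(se_days),
    n = as.integer(n),
    developed = as.logical(developed),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$stage, df$sex, df$temperature_C), , drop = FALSE]
  rownames(df) <- NULL
  validate_dev_dataset(df)
  structure(df, class = c("dev_dataset", "data.frame"), label = label)
}

#' Validate a development-observation table
#'
#' Checks the row-level invariants (positive finite durations for developed
#' rows, absent durations for failure rows, `n = 0` only on failure rows) and
#' the table-level invariant that (stage, sex, temperature) triples are
#' unique. Violations are reported with row numbers.
#'
#' @param df data frame with the `dev_dataset` columns.
#' @return Invisibly `TRUE`; stops with a diagnostic message otherwise.
#' @export
validate_dev_dataset <- function(df) {
  req <- c("stage", "sex", "temperature_C", "mean_days", "se_days", "n",
           "developed")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$stage %in% STAGES) {
      bad <- c(bad, sprintf("row %d: unknown stage '%s'", i, row$stage))
    }
    if (!row$sex %in% SEXES) {
      bad <- c(bad, sprintf("row %d: unknown sex '%s'", i, row$sex))
    }
    if (!is.finite(row$temperature_C)) {
      bad <- c(bad, sprintf("row %d: non-numeric temperature", i))
    }
    if (isTRUE(row$developed)) {
      if (!is.finite(row$mean_days) || row$mean_days <= 0) {
        bad <- c(bad, sprintf(
          "row %d: mean_days must be finite and > 0 for a developed observation (got %s)",
          i, format(row$mean_days)))
      }
      if (!is.na(row$n) && row$n == 0L) {
        bad <- c(bad, sprintf("row %d: n = 0 only permitted when developed = FALSE", i))
      }
    } else {
      if (!is.na(row$mean_days)) {
        bad <- c(bad, sprintf("row %d: mean_days must be absent when developed = FALSE", i))
      }
    }
    if (!is.na(row$se_days) && row$se_days < 0) {
      bad <- c(bad, sprintf("row %d: se_days must be >= 0", i))
    }
    if (!is.na(row$n) && row$n < 0L) {
      bad <- c(bad, sprintf("row %d: n must be >= 0", i))
    }
  }
  key <- paste(df$stage, df$sex, df$temperature_C)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    bad <- c(bad, sprintf("row %d: duplicate (stage, sex, temperature) triple", dup))
  }
  if (length(bad) > 0L) {
    stop("invalid dev_dataset:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a development dataset from delimited text
#'
#' Expects a UTF-8 header row naming the seven `dev_dataset` columns
#' (`stage,sex,temperature_C,mean_days,se_days,n,developed`). Comma is the
#' default delimiter; tab is accepted via `sep = "\t"`.
#'
#' @param path file path.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @param label dataset label; defaults to the file name.
#' @return A validated [dev_dataset].
#' @export
read_dev_table <- function(path, sep = ",", label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("stage", "sex", "temperature_C", "mean_days", "se_days", "n",
           "developed")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("format error: header missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(dev_dataset(character(0), character(0), numeric(0), numeric(0),
                       numeric(0), integer(0), logical(0), label = label))
  }
  for (col in c("temperature_C", "mean_days", "se_days")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("parse error: non-numeric %s at row %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  dev_dataset(df$stage, df$sex, df$temperature_C, df$mean_days, df$se_days,
              as.integer(df$n), as.logical(df$developed), label = label)
}

#' Write a development dataset as delimited text
#'
#' @param ds a [dev_dataset].
#' @param path output file path.
#' @param sep field delimiter.
#' @return Invisibly `path`.
#' @export
write_dev_table <- function(ds, path, sep = ",") {
  utils::write.table(as.data.frame(ds), path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Development times of Stethorus gilvifrons at constant temperatures
#'
#' The transcribed published development-time table for the ladybird
#' *Stethorus gilvifrons* fed *Tetranychus urticae*: mean +/- SE days and
#' cohort sizes for egg, larval and pupal stages of females and males at six
#' constant temperatures (15, 20, 25, 27, 30, 34 degrees C), plus an
#' egg-failure record at 38 degrees C (no eggs hatched there). Total
#' (egg-to-adult) durations are stored as separate `stage = "total"` rows
#' taken from the published egg-to-adult means, not as sums of stage means:
#' the published totals derive from individual-level data and differ from
#' stage sums by up to 0.2 d.
#'
#' @return A [dev_dataset] with 49 rows: 3 stages x 2 sexes x 6 temperatures,
#'   12 direct total-duration rows, and one failure record at 38 degrees C.
#' @examples
#' ds <- stethorus_table2()
#' subset(as.data.frame(ds), stage == "egg" & sex == "female")
#' @export
stethorus_table2 <- function() {
  temps <- c(15, 20, 25, 27, 30, 34)
  # per-stage cohort sizes are shared between sexes
  n_egg <- c(139L, 125L, 115L, 118L, 118L, 92L)
  n_larva <- c(17L, 49L, 70L, 79L, 70L, 59L)
  n_pupa <- c(17L, 39L, 64L, 62L, 62L, 58L)

  f_egg <- c(15.7, 8.7, 3.3, 3.2, 3.0, 3.7)
  f_egg_se <- c(0.5, 0.2, 0.0, 0.1, 0.0, 0.0)
  f_larva <- c(33.9, 15.1, 7.5, 7.2, 6.4, 5.3)
  f_larva_se <- c(0.7, 0.4, 0.3, 0.1, 0.2, 0.1)
  f_pupa <- c(11.8, 7.7, 3.5, 2.8, 2.9, 2.6)
  f_pupa_se <- c(0.2, 0.4, 0.1, 0.0, 0.1, 0.0)

  m_egg <- c(15.7, 7.3, 3.8, 3.5, 3.0, 3.5)
  m_egg_se <- c(0.5, 0.1, 0.1, 0.1, 0.0, 0.1)
  m_larva <- c(35.4, 14.4, 6.6, 7.0, 6.3, 5.8)
  m_larva_se <- c(1.0, 0.3, 0.3, 0.2, 0.1, 0.1)
  m_pupa <- c(12.1, 6.6, 2.8, 2.9, 2.9, 2.9)
  m_pupa_se <- c(0.2, 0.3, 0.1, 0.0, 0.0, 0.0)

  # egg-to-adult totals as published (direct, not stage sums); SEs not printed
  f_total <- c(61.4, 31.6, 14.4, 13.3, 12.5, 11.7)
  m_total <- c(63.2, 28.5, 13.2, 13.4, 12.2, 12.3)

  stage <- c(rep(c("egg", "larva", "pupa"), each = 6L, times = 2L),
             rep("total", 12L), "egg")
  sex <- c(rep(c("female", "male"), each = 18L),
           rep(c("female", "male"), each = 6L), "pooled")
  temperature_C <- c(rep(temps, 8L), 38)
  mean_days <- c(f_egg, f_larva, f_pupa, m_egg, m_larva, m_pupa,
                 f_total, m_total, NA_real_)
  se_days <- c(f_egg_se, f_larva_se, f_pupa_se, m_egg_se, m_larva_se,
               m_pupa_se, rep(NA_real_, 12L), NA_real_)
  n <- c(rep(c(n_egg, n_larva, n_pupa), 2L), n_pupa, n_pupa, 0L)
  developed <- c(rep(TRUE, 48L), FALSE)

  dev_dataset(stage, sex, temperature_C, mean_days, se_days, n, developed,
              label = "S. gilvifrons on T. urticae, six constant temperatures")
}

#' Pool the two sexes of a development dataset
#'
#' Collapses female and male rows of each (stage, temperature) cell into one
#' `sex = "pooled"` row, taking the cohort-size-weighted mean of the mean
#' durations and combining standard errors of the two independent means.
#' Rows already pooled, and failure rows, are passed through.
#'
#' @param ds a [dev_dataset].
#' @return A [dev_dataset] in which every developed row has `sex = "pooled"`.
#' @export
pool_sexes <- function(ds) {
  df <- as.data.frame(ds)
  keep <- df[df$sex == "pooled" | !df$developed, , drop = FALSE]
  keep$sex <- "pooled"
  two <- df[df$sex != "pooled" & df$developed, , drop = FALSE]
  if (nrow(two) > 0L) {
    key <- interaction(two$stage, two$temperature_C, drop = TRUE)
    pooled <- do.call(rbind, lapply(split(two, key), function(g) {
      w <- g$n
      if (any(is.na(w)) || sum(w) == 0) w <- rep(1, nrow(g))
      m <- sum(w * g$mean_days) / sum(w)
      se <- if (all(!is.na(g$se_days))) {
        sqrt(sum((w / sum(w))^2 * g$se_days^2))
      } else NA_real_
      data.frame(stage = g$stage[1L], sex = "pooled",
                 temperature_C = g$temperature_C[1L], mean_days = m,
                 se_days = se, n = as.integer(sum(g$n)), developed = TRUE,
                 stringsAsFactors = FALSE)
    }))
    keep <- rbind(keep, pooled)
  }
  # drop duplicate failure rows created by relabelling
  keep <- keep[!duplicated(paste(keep$stage, keep$sex, keep$temperature_C)), ]
  dev_dataset(keep$stage, keep$sex, keep$temperature_C, keep$mean_days,
              keep$se_days, keep$n, keep$developed, label = attr(ds, "label"))
}

#' Convert development durations to rates
#'
#' Extracts one (stage, sex) slice of a dataset within a closed temperature
#' interval and converts each developed observation's mean duration to a
#' development rate r = 1/d (per day). Failure records are excluded unless
#' `include_failures = TRUE`, in which case they contribute rate 0.
#'
#' @param ds a [dev_dataset].
#' @param stage,sex slice selectors.
#' @param range closed temperature interval `c(lo, hi)` in degrees C.
#' @param include_failures logical; include failure temperatures as rate 0.
#' @return A data frame of class `rate_points` with columns `temperature`,
#'   `rate`, `weight` (default 1) and `mean_days`, ordered by temperature.
#' @examples
#' dev_rates(stethorus_table2(), "egg", "female", range = c(15, 27))
#' @export
dev_rates <- function(ds, stage, sex, range = c(-Inf, Inf),
                      include_failures = FALSE) {
  df <- as.data.frame(ds)
  sel <- df$stage == stage & df$sex == sex &
    df$temperature_C >= range[1] & df$temperature_C <= range[2]
  df <- df[sel, , drop = FALSE]
  if (!include_failures) df <- df[df$developed, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop(sprintf("empty slice: no observations for (%s, %s) in [%s, %s]",
                 stage, sex, range[1], range[2]), call. = FALSE)
  }
  rate <- ifelse(df$developed, 1 / df$mean_days, 0)
  out <- data.frame(temperature = df$temperature_C, rate = rate,
                    weight = 1, mean_days = df$mean_days,
                    stringsAsFactors = FALSE)
  out <- out[order(out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rate_points", "data.frame")
  out
}

#' @export
print.dev_dataset <- function(x, ...) {
  cat(sprintf("<dev_dataset> %d observations  label: %s\n", nrow(x),
              attr(x, "label")))
  print(as.data.frame(x), ...)
  invisible(x)
}
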