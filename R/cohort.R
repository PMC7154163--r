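#' Cohort construction and validation
#'
#' A cohort is a tibble with one row per subject: a follow-up time column, a
#' 0/1 event indicator column, and typed predictor columns.  Variable kinds
#' drive split-candidate enumeration:
#'
#' * `binary` — one threshold candidate;
#' * `genotype012` — additive SNP coding (number of alternative alleles);
#'   two candidates, dominant (`{0}` vs `{1,2}`) and recessive (`{0,1}` vs
#'   `{2}`);
#' * `ordered3` — three ordered levels (e.g. low/intermediate/high
#'   immunogenicity), two threshold candidates;
#' * `continuous` — thresholds at midpoints between consecutive distinct
#'   observed values (or quartile cuts, see [grow_tree()]);
#' * `categorical` — unordered; one-vs-rest candidate per level.
#'
#' @param data A data frame; one row per subject.
#' @param time,event Names of the follow-up time and event indicator
#'   columns.
#' @param kinds Named character vector mapping predictor columns to kinds.
#'   Columns not named in `kinds` (other than `time`/`event`/`id`) are
#'   inferred: 0/1 columns become `binary`, character/factor columns
#'   `categorical`, everything else `continuous`.  SNP columns must be
#'   declared `genotype012` explicitly.
#' @param id Optional name of a subject id column; defaults to row order.
#' @return The validated tibble with class `cure_cohort` and attributes
#'   `time_col`, `event_col`, `id_col`, `kinds`.
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 0),
#'                     sex = c(0, 1, 1), age = c(40, 55, 61))
#' co <- as_cohort(d)
#' cohort_kinds(co)
#' @export
as_cohort <- function(data, time = "time", event = "event", kinds = NULL,
                      id = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  for (col in c(time, event, id)) {
    if (!col %in% names(data)) {
      stop("as_cohort: column '", col, "' not found", call. = FALSE)
    }
  }
  tv <- data[[time]]
  if (!is.numeric(tv) || any(is.na(tv)) || any(tv < 0)) {
    stop("as_cohort: '", time, "' must be numeric, nonnegative, complete")
  }
  ev <- data[[event]]
  if (!is.numeric(ev) || any(is.na(ev)) || !all(ev %in% c(0, 1))) {
    stop("as_cohort: '", event, "' must contain only 0/1")
  }
  feat <- setdiff(names(data), c(time, event, id))
  kinds <- infer_kinds(data, feat, kinds)
  for (v in names(kinds)) {
    x <- data[[v]]
    switch(kinds[[v]],
      genotype012 = {
        if (!is.numeric(x) || !all(x[!is.na(x)] %in% 0:2)) {
          stop("as_cohort: genotype column '", v,
               "' has values outside {0, 1, 2}")
        }
      },
      binary = {
        if (!is.numeric(x) || !all(x[!is.na(x)] %in% 0:1)) {
          stop("as_cohort: binary column '", v, "' has values outside {0, 1}")
        }
      },
      ordered3 = {
        if (!is.numeric(x) || !all(x[!is.na(x)] %in% 1:3)) {
          stop("as_cohort: ordered3 column '", v,
               "' has values outside {1, 2, 3}")
        }
      },
      continuous = {
        if (!is.numeric(x)) stop("as_cohort: continuous column '", v,
                                 "' is not numeric")
      },
      categorical = {
        data[[v]] <- as.character(x)
      },
      stop("as_cohort: unknown kind '", kinds[[v]], "' for column '", v, "'")
    )
  }
  structure(data,
            class = c("cure_cohort", class(tibble::tibble())),
            time_col = time, event_col = event, id_col = id,
            kinds = kinds)
}

infer_kinds <- function(data, feat, kinds) {
  kinds <- kinds %||% character(0)
  bad <- setdiff(names(kinds), feat)
  if (length(bad)) stop("as_cohort: kinds given for unknown columns: ",
                        paste(bad, collapse = ", "))
  ok <- c("binary", "continuous", "categorical", "genotype012", "ordered3")
  if (!all(kinds %in% ok)) {
    stop("as_cohort: unknown kinds: ",
         paste(setdiff(kinds, ok), collapse = ", "))
  }
  for (v in setdiff(feat, names(kinds))) {
    x <- data[[v]]
    kinds[[v]] <-
      if (is.character(x) || is.factor(x)) "categorical"
      else if (is.numeric(x) && all(x[!is.na(x)] %in% 0:1)) "binary"
      else "continuous"
  }
  kinds[feat]
}

#' @rdname as_cohort
#' @param cohort A `cure_cohort`.
#' @export
cohort_kinds <- function(cohort) attr(cohort, "kinds")

cohort_time  <- function(cohort) cohort[[attr(cohort, "time_col")]]
cohort_event <- function(cohort) cohort[[attr(cohort, "event_col")]]

cohort_ids <- function(cohort) {
  idc <- attr(cohort, "id_col")
  if (is.null(idc)) seq_len(nrow(cohort)) else cohort[[idc]]
}

# Numeric feature matrix for the tree engine; categorical levels are mapped
# to integer codes, with the level table kept alongside.
cohort_matrix <- function(cohort) {
  kinds <- cohort_kinds(cohort)
  lev <- list()
  cols <- lapply(names(kinds), function(v) {
    x <- cohort[[v]]
    if (kinds[[v]] == "categorical") {
      f <- factor(x)
      lev[[v]] <<- levels(f)
      as.numeric(f)
    } else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(kinds)
  list(X = X, kinds = kinds, levels = lev)
}

reattach_cohort <- function(data, template) {
  structure(tibble::as_tibble(data),
            class = class(template),
            time_col = attr(template, "time_col"),
            event_col = attr(template, "event_col"),
            id_col = attr(template, "id_col"),
            kinds = attr(template, "kinds")[intersect(
              names(attr(template, "kinds")), names(data))])
}

#' Read / write a cohort with a plain-text schema sidecar
#'
#' The schema is a `key=value` file mapping each column to its kind, with
#' the reserved kinds `time`, `event` and `id` marking the outcome and id
#' columns.  PLINK-RAW-style additive genotype columns (0/1/2 with missing)
#' are declared with kind `genotype012`.
#'
#' @param path CSV (or TSV, by extension) cohort file with a header row.
#' @param schema Path to the schema file.
#' @return A [as_cohort()] cohort.
#' @export
read_cohort <- function(path, schema) {
  sc <- read_config(schema)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  time_col  <- names(sc)[sc == "time"]
  event_col <- names(sc)[sc == "event"]
  id_col    <- names(sc)[sc == "id"]
  if (length(time_col) != 1 || length(event_col) != 1) {
    stop("read_cohort: schema must name exactly one time and one event column")
  }
  kinds <- unlist(sc[!sc %in% c("time", "event", "id")])
  as_cohort(raw, time = time_col, event = event_col, kinds = kinds,
            id = if (length(id_col)) id_col else NULL)
}

#' @rdname read_cohort
#' @param cohort A `cure_cohort`.
#' @export
write_cohort <- function(cohort, path, schema) {
  stopifnot(inherits(cohort, "cure_cohort"))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(tibble::as_tibble(cohort), path, delim = delim)
  sc <- as.list(cohort_kinds(cohort))
  sc[[attr(cohort, "time_col")]] <- "time"
  sc[[attr(cohort, "event_col")]] <- "event"
  if (!is.null(attr(cohort, "id_col"))) sc[[attr(cohort, "id_col")]] <- "id"
  write_config(sc, schema)
  invisible(path)
}

#' Flat key=value config files
#'
#' Minimal plain-text serialisation used for schema sidecars and CLI
#' parameter sets: one `key=value` per line, `#` comments allowed.
#'
#' @param path File path.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("read_config: malformed line(s): ",
                     paste(lines[bad], collapse = "; "))
  out <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(out) <- trimws(vapply(kv, `[[`, "", 1))
  # numbers come back as numerics
  lapply(out, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
}

#' @rdname read_config
#' @param config Named list or vector of scalar values.
#' @export
write_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  writeLines(paste0(names(config), "=", vapply(config, format, "")), path)
  invisible(path)
}

#' Impute missing predictor values
#'
#' Continuous columns get the mean of the observed values; binary,
#' categorical, genotype and ordered columns get the most common observed
#' class (ties broken toward the lowest value).  Outcome columns must be
#' complete already.
#'
#' @param cohort A `cure_cohort`.
#' @return The cohort with no missing predictor values; the number of
#'   imputed cells per column is attached as attribute `imputation_report`.
#' @export
impute_missing <- function(cohort) {
  stopifnot(inherits(cohort, "cure_cohort"))
  kinds <- cohort_kinds(cohort)
  report <- integer(0)
  for (v in names(kinds)) {
    x <- cohort[[v]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) stop("impute_missing: column '", v, "' entirely missing")
    fill <- if (kinds[[v]] == "continuous") {
      mean(x[!miss])
    } else {
      obs <- x[!miss]
      tab <- table(obs)
      modes <- names(tab)[tab == max(tab)]
      m <- sort(modes)[1]
      if (is.numeric(obs)) as.numeric(m) else m
    }
    x[miss] <- fill
    cohort[[v]] <- x
    report[[v]] <- sum(miss)
  }
  attr(cohort, "imputation_report") <- report
  cohort
}

#' Filter genotype columns by minor allele frequency
#'
#' Keeps genotype columns whose minor allele frequency exceeds `threshold`.
#' The allele frequency is estimated from additive genotype counts as
#' `(n1 + 2 n2) / (2 n)` and folded to `<= 0.5`.
#'
#' @param cohort A `cure_cohort`.
#' @param threshold MAF cut; columns with MAF `<= threshold` are dropped.
#'   The default mirrors the common-SNP convention of keeping MAF > 25%.
#' @return The filtered cohort; the number of dropped columns is attached as
#'   attribute `maf_dropped`.
#' @export
maf_filter <- function(cohort, threshold = 0.25) {
  stopifnot(inherits(cohort, "cure_cohort"),
            threshold >= 0, threshold < 0.5)
  kinds <- cohort_kinds(cohort)
  geno <- names(kinds)[kinds == "genotype012"]
  drop <- character(0)
  for (v in geno) {
    x <- cohort[[v]]
    x <- x[!is.na(x)]
    af <- sum(x) / (2 * length(x))
    maf <- min(af, 1 - af)
    if (maf <= threshold) drop <- c(drop, v)
  }
  out <- cohort[, setdiff(names(cohort), drop), drop = FALSE]
  out <- reattach_cohort(out, cohort)
  attr(out, "maf_dropped") <- length(drop)
  out
}

#' Drug to immunogenicity-group map
#'
#' The default grouping of the eight biotherapies into low, intermediate and
#' high immunogenicity classes used by [encode_treatment()].
#'
#' @return Named character vector `drug -> group`.
#' @export
drug_immunogenicity_groups <- function() {
  c("Etanercept"    = "low",
    "IFNbeta-1a-im" = "low",
    "Tocilizumab"   = "intermediate",
    "Infliximab"    = "intermediate",
    "IFNbeta-1a-sc" = "intermediate",
    "Rituximab"     = "high",
    "Adalimumab"    = "high",
    "IFNbeta-1b-sc" = "high")
}

#' Encode treatment labels
#'
#' Turns a vector of drug labels into (a) an ordered three-level
#' immunogenicity score (low = 1, intermediate = 2, high = 3) and (b) one
#' 0/1 dummy column per distinct drug (one drug vs the others).
#'
#' @param labels Character vector of drug labels.
#' @param map Named character vector mapping each drug to
#'   `"low"`/`"intermediate"`/`"high"`; defaults to
#'   [drug_immunogenicity_groups()].
#' @return Tibble with column `immunogenicity` (ordered3 coding) and one
#'   `drug_<label>` dummy per distinct drug.
#' @export
encode_treatment <- function(labels, map = drug_immunogenicity_groups()) {
  stopifnot(is.character(labels), !anyNA(labels))
  unknown <- setdiff(unique(labels), names(map))
  if (length(unknown)) {
    stop("encode_treatment: unmapped drug label(s): ",
         paste(unknown, collapse = ", "))
  }
  score <- c(low = 1, intermediate = 2, high = 3)[map[labels]]
  out <- tibble::tibble(immunogenicity = as.numeric(score))
  for (d in sort(unique(labels))) {
    out[[paste0("drug_", gsub("[^A-Za-z0-9]+", "_", d))]] <-
      as.numeric(labels == d)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
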