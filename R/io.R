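#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig dialect: records start with \code{LM=k}, followed by
#' k whitespace-separated coordinate lines; \code{ID=}, \code{IMAGE=} and
#' \code{SCALE=} keys are honored (SCALE multiplies the coordinates).
#' Index metadata (individual, part, replicate) is parsed from the ID via
#' a regular expression with three capture groups; the default expects
#' \code{individual_part_replicate}. Landmark indices are 1-based
#' throughout the package.
#'
#' @param path TPS file path.
#' @param idPattern regex with capture groups for individual, part,
#'   replicate; set NULL to skip parsing (IDs kept as \code{id} only).
#' @return a [LandmarkSet-class]; the info includes the raw \code{id}.
#' @export
readTPS <- function(path, idPattern = "^(.+)_([^_]+)_([^_]+)$") {
  lines <- readLines(path)
  lines <- trimws(lines)
  configs <- list(); ids <- character(); scales <- numeric()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("malformed TPS file at line ", i, ": expected LM= header")
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("malformed LM count at line ", i)
    if (i + k > length(lines))
      stop("LM count mismatch at line ", i, ": file ends early")
    co <- lines[(i + 1L):(i + k)]
    mat <- do.call(rbind, lapply(seq_along(co), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(co[j], "\\s+")[[1L]]))
      if (any(is.na(v)))
        stop("malformed coordinate line ", i + j, call. = FALSE)
      v
    }))
    i <- i + k + 1L
    id <- NA_character_; scl <- 1
    while (i <= length(lines) && lines[i] != "" &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      kv <- lines[i]
      if (grepl("^ID\\s*=", kv, ignore.case = TRUE))
        id <- sub("^ID\\s*=\\s*", "", kv, ignore.case = TRUE)
      else if (grepl("^SCALE\\s*=", kv, ignore.case = TRUE))
        scl <- as.numeric(sub("^SCALE\\s*=\\s*", "", kv,
                              ignore.case = TRUE))
      else if (!grepl("^IMAGE\\s*=", kv, ignore.case = TRUE))
        stop("unrecognized TPS key at line ", i, ": ", kv)
      i <- i + 1L
    }
    configs[[length(configs) + 1L]] <- mat * scl
    ids <- c(ids, if (is.na(id)) as.character(length(configs)) else id)
    scales <- c(scales, scl)
  }
  if (!length(configs)) stop("no records found in ", path)
  info <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(idPattern)) {
    m <- regmatches(ids, regexec(idPattern, ids))
    ok <- lengths(m) == 4L
    if (!all(ok))
      warning(sum(!ok), " ID(s) did not match idPattern; ",
              "index metadata left as NA")
    getg <- function(j) vapply(seq_along(m), function(i)
      if (ok[i]) m[[i]][j + 1L] else NA_character_, "")
    info$individual <- getg(1L)
    info$part <- utils::type.convert(getg(2L), as.is = TRUE)
    info$replicate <- utils::type.convert(getg(3L), as.is = TRUE)
  }
  ls <- landmarkSet(configs, info = info)
  ls
}

#' Write landmark configurations to a TPS file
#'
#' @param x a [LandmarkSet-class].
#' @param path output path.
#' @param digits coordinate decimals (default 6).
#' @return the path, invisibly.
#' @export
writeTPS <- function(x, path, digits = 6L) {
  info <- x@info
  ids <- if (!is.null(info$id)) info$id
  else paste(info$individual, info$part, info$replicate, sep = "_")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(length(x))) {
    m <- getConfig(x, i)
    writeLines(sprintf("LM=%d", nrow(m)), con)
    writeLines(apply(format(round(m, digits), nsmall = digits,
                            trim = TRUE, scientific = FALSE),
                     1L, paste, collapse = " "), con)
    writeLines(sprintf("ID=%s", ids[i]), con)
  }
  invisible(path)
}

#' Read/write landmark data in long CSV format
#'
#' Long format: one row per (configuration, landmark) with columns
#' \code{individual}, \code{part}, \code{replicate}, \code{landmark},
#' \code{x}, \code{y}.
#'
#' @param path CSV path.
#' @return [readLandmarkCSV()]: a [LandmarkSet-class];
#'   [writeLandmarkCSV()]: the path, invisibly.
#' @export
readLandmarkCSV <- function(path) {
  df <- read.csv(path)
  need <- c("individual", "part", "replicate", "landmark", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CSV is missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- .key(df$individual, df$part, df$replicate)
  ord <- order(match(key, unique(key)), df$landmark)
  df <- df[ord, ]
  key <- key[ord]
  ks <- table(factor(key, levels = unique(key)))
  if (length(unique(as.vector(ks))) != 1L)
    stop("configurations have differing landmark counts")
  k <- as.vector(ks)[1L]
  n <- length(ks)
  coords <- array(0, dim = c(k, 2L, n))
  coords[, 1L, ] <- matrix(df$x, k)
  coords[, 2L, ] <- matrix(df$y, k)
  first <- !duplicated(key)
  landmarkSet(coords,
              info = data.frame(individual = df$individual[first],
                                part = df$part[first],
                                replicate = df$replicate[first]))
}

#' @rdname readLandmarkCSV
#' @param x a [LandmarkSet-class].
#' @export
writeLandmarkCSV <- function(x, path) {
  k <- dim(x@coords)[1L]
  info <- x@info[rep(seq_len(length(x)), each = k),
                 c("individual", "part", "replicate"), drop = FALSE]
  df <- cbind(info,
              landmark = rep(seq_len(k), length(x)),
              x = as.vector(x@coords[, 1L, ]),
              y = as.vector(x@coords[, 2L, ]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# published column order of the effect tables
.tableColumns <- c(effect = "effect", convDf = "conv_df",
                   shapeDf = "shape_df", ss = "ss", ms = "ms", f = "f",
                   pParam = "p_param", pPerm = "p_perm",
                   pillai = "pillai", pillaiPParam = "pillai_p_param",
                   pillaiPPerm = "pillai_p_perm")

#' Write an effect table to CSV
#'
#' Columns in the published order (effect, conventional df, shape df, SS,
#' MS, F, parametric P, permutation P, Pillai's trace and its P values),
#' numbers at 6 significant digits; output is deterministic.
#'
#' @param fit an [EffectTable-class] (or its data.frame).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEffectTable <- function(fit, path) {
  tab <- if (is(fit, "EffectTable")) fit@table else fit
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], signif, digits = 6L)
  names(tab) <- .tableColumns[names(tab)]
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read back an effect table CSV
#' @param path CSV path written by [writeEffectTable()].
#' @return a data.frame with the package's internal column names.
#' @export
readEffectTable <- function(path) {
  tab <- read.csv(path)
  names(tab) <- names(.tableColumns)[match(names(tab), .tableColumns)]
  tab
}

#' Reference ANOVA values for the lantern case study
#'
#' The published Procrustes ANOVA, MANOVA-free columns (conventional df,
#' shape df, SS, MS, F) of the three symmetry analyses and the
#' centroid-size ANOVA of the sea-urchin lantern dataset (10 lanterns x
#' 5 pyramids x 2 replicates, 12 landmarks). Shipped as a plain-text
#' fixture; used to certify degrees-of-freedom bookkeeping and F-ratio
#' construction without access to the archived raw data.
#'
#' @return data.frame with columns analysis, effect, conv_df, shape_df,
#'   ss, ms, f.
#' @export
lanternReferenceTable <- function() {
  read.csv(system.file("extdata", "lantern_reference_anova.csv",
                       package = "nestsym"))
}
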