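# TSV serialization with '#' provenance headers for all numeric artifacts.

.provenance_header <- function(extra = character()) {
  c(paste0("# pairscape ", as.character(utils::packageVersion("pairscape"))),
    paste0("# date ", format(Sys.time(), "%Y-%m-%d")),
    extra)
}

.spec_header <- function(spec) {
  sprintf("# grid dims=%d mins=%s maxs=%s nbins=%s periodic=%s names=%s",
          spec$dims,
          paste(spec$mins, collapse = ","), paste(spec$maxs, collapse = ","),
          paste(spec$nbins, collapse = ","), paste(spec$periodic, collapse = ","),
          paste(spec$names, collapse = ","))
}

.write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write CV/force samples as TSV
#' @param samples data.frame from [sample_langevin()] (one walker).
#' @param path Output path.
#' @param seed Optional seed echoed into the header.
#' @return Invisibly, the path.
#' @export
write_samples_tsv <- function(samples, path, seed = NULL) {
  hdr <- .provenance_header(if (!is.null(seed)) paste0("# seed ", seed))
  .write_tsv(samples, path, hdr)
}

#' Read CV/force samples from TSV
#' @param path Input path.
#' @return data.frame of samples.
#' @export
read_samples_tsv <- function(path) .read_tsv(path)

#' Write a mean-force grid as TSV
#' @param grid A `mean_force_grid`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_grid_tsv <- function(grid, path) {
  spec <- grid$spec
  centers <- .all_centers(spec)
  df <- data.frame(centers)
  names(df) <- spec$names[seq_len(spec$dims)]
  df$n <- grid$n
  for (k in seq_len(spec$dims)) {
    df[[paste0("mean_force_", k)]] <- grid$mean[, k]
    df[[paste0("m2_", k)]] <- grid$m2[, k]
  }
  .write_tsv(df, path, c(.provenance_header(), .spec_header(spec)))
}

#' Read a mean-force grid from TSV
#' @param path Input path.
#' @return A `mean_force_grid`.
#' @export
read_grid_tsv <- function(path) {
  hdr <- grep("^# grid ", readLines(path, n = 20), value = TRUE)
  if (length(hdr) == 0) stop("missing '# grid' header in ", path)
  gv <- function(key) strsplit(sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr), ",")[[1]]
  spec <- grid_spec(as.numeric(gv("mins")), as.numeric(gv("maxs")),
                    as.integer(gv("nbins")), as.logical(gv("periodic")),
                    names = gv("names"))
  df <- .read_tsv(path)
  grid <- .empty_grid(spec)
  grid$n <- as.integer(df$n)
  for (k in seq_len(spec$dims)) {
    grid$mean[, k] <- df[[paste0("mean_force_", k)]]
    grid$m2[, k] <- df[[paste0("m2_", k)]]
  }
  grid
}

#' Write a free-energy surface as TSV
#' @param surface A `fe_surface`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_surface_tsv <- function(surface, path) {
  spec <- surface$spec
  df <- data.frame(.all_centers(spec))
  names(df) <- spec$names[seq_len(spec$dims)]
  df$value <- surface$value
  df$stderr <- surface$stderr
  df$mask <- as.integer(surface$mask)
  if (!is.null(surface$n)) df$n <- surface$n
  .write_tsv(df, path, c(.provenance_header(), .spec_header(spec)))
}

#' Read a free-energy surface from TSV
#' @param path Input path (as written by [write_surface_tsv()]).
#' @return A `fe_surface`.
#' @export
read_surface_tsv <- function(path) {
  hdr <- grep("^# grid ", readLines(path, n = 20), value = TRUE)
  if (length(hdr) == 0) stop("missing '# grid' header in ", path)
  gv <- function(key) strsplit(sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr), ",")[[1]]
  spec <- grid_spec(as.numeric(gv("mins")), as.numeric(gv("maxs")),
                    as.integer(gv("nbins")), as.logical(gv("periodic")),
                    names = gv("names"))
  df <- .read_tsv(path)
  structure(list(spec = spec, value = df$value, stderr = df$stderr,
                 mask = as.logical(df$mask),
                 n = if ("n" %in% names(df)) as.integer(df$n)),
            class = "fe_surface")
}

#' Read a 1D free-energy profile from TSV
#' @param path Input path (as written by [write_profile_tsv()]).
#' @return A `fe_profile`.
#' @export
read_profile_tsv <- function(path) {
  hdr <- grep("^# profile ", readLines(path, n = 20), value = TRUE)
  temperature <- if (length(hdr) > 0) {
    as.numeric(sub(".*temperature=([0-9.eE+-]+).*", "\\1", hdr))
  } else 300
  df <- .read_tsv(path)
  structure(list(axis = names(df)[1], centers = df[[1]], value = df$value,
                 stderr = df$stderr, mask = as.logical(df$mask),
                 temperature = temperature, periodic = FALSE),
            class = "fe_profile")
}

#' Write a 1D free-energy profile as TSV
#' @param profile A `fe_profile`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(axis = profile$centers, value = profile$value,
                   stderr = profile$stderr, mask = as.integer(profile$mask))
  names(df)[1] <- profile$axis
  hdr <- c(.provenance_header(),
           sprintf("# profile axis=%s temperature=%g", profile$axis,
                   profile$temperature))
  .write_tsv(df, path, hdr)
}
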