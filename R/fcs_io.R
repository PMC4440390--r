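#' Write a per-cell parameter table as an FCS 3.1 list-mode file
#'
#' Serialises a numeric per-cell table (lifetime, intensity, burst
#' duration, FRET efficiency, ...) as a Flow Cytometry Standard 3.1 file
#' with a single DATA segment storing 32-bit little-endian floats
#' (`$DATATYPE F`, `$MODE L`, `$BYTEORD 1,2,3,4`), the most widely read
#' FCS flavour. Parameter names are taken from the column names;
#' non-ASCII or delimiter characters are replaced deterministically with
#' `_` (with a warning).
#'
#' @param table data.frame of numeric columns, one row per event.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("empty table: nothing to write")
  if (!all(vapply(table, is.numeric, TRUE)))
    stop("all FCS parameters must be numeric")
  pnames <- sanitize_fcs_names(names(table))
  n_par <- ncol(table)
  n_tot <- nrow(table)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$TOT" = as.character(n_tot), "$PAR" = as.character(n_par))
  for (i in seq_len(n_par)) {
    rng <- max(abs(table[[i]]), 1)
    kw[[sprintf("$P%dN", i)]] <- pnames[i]
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dR", i)]] <- format(ceiling(rng), scientific = FALSE)
  }
  # fixed-width offset placeholders keep the TEXT length independent of
  # the values substituted in
  delim <- "/"
  text_body <- paste0(delim,
                      paste(rbind(names(kw), unname(kw)), collapse = delim),
                      delim)
  pad10 <- function(x) formatC(x, width = 10, flag = "0", format = "d")
  text_len <- nchar(sub("%BD%", pad10(0), sub("%ED%", pad10(0), text_body),
                        fixed = TRUE), type = "bytes")
  header_len <- 58L
  text_start <- header_len
  text_end <- text_start + text_len - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n_par * n_tot - 1L
  text_final <- sub("%BD%", pad10(data_start),
                    sub("%ED%", pad10(data_end), text_body, fixed = TRUE),
                    fixed = TRUE)

  pad8 <- function(x) formatC(x, width = 8, format = "d")
  header <- paste0("FCS3.1    ", pad8(text_start), pad8(text_end),
                   pad8(if (data_end <= 99999999) data_start else 0),
                   pad8(if (data_end <= 99999999) data_end else 0),
                   pad8(0), pad8(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_final, con, eos = NULL)
  # row-major event data as 32-bit floats
  dat <- as.vector(t(as.matrix(table)))
  writeBin(dat, con, size = 4L, endian = "little")
  invisible(path)
}

sanitize_fcs_names <- function(nm) {
  clean <- gsub("[^A-Za-z0-9_.-]", "_", nm)
  clean[clean == ""] <- "_"
  if (any(clean != nm))
    warning("parameter names sanitized for FCS: ",
            paste(nm[clean != nm], collapse = ", "))
  make.unique(clean, sep = "_")
}

#' Read an FCS list-mode file written by [write_fcs()]
#'
#' Minimal FCS reader covering the subset this package writes (and most
#' instrument files of the same flavour): FCS 3.0/3.1 header, single DATA
#' segment, `$DATATYPE F`, `$MODE L`, little- or big-endian byte order.
#'
#' @param path FCS file path.
#' @return List with `data` (data.frame, one row per event) and
#'   `keywords` (named character vector of the TEXT segment).
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  magic <- rawToChar(raw[1:6])
  if (!magic %in% c("FCS3.0", "FCS3.1"))
    stop("not an FCS 3.x file: ", magic)
  off <- function(i) {
    s <- 10L + (i - 1L) * 8L + 1L
    as.integer(trimws(rawToChar(raw[s:(s + 7L)])))
  }
  text_start <- off(1L); text_end <- off(2L)
  text <- rawToChar(raw[(text_start + 1L):(text_end + 1L)])
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substr(text, 2L, nchar(text)), delim, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1L, length(parts), 2L)]
  vals <- parts[seq(2L, length(parts), 2L)]
  kw <- setNames(vals, toupper(keys))

  if (kw[["$DATATYPE"]] != "F" || kw[["$MODE"]] != "L")
    stop("unsupported FCS layout (need $DATATYPE F, $MODE L)")
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  data_start <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(data_start) || data_start == 0L) data_start <- off(3L)
  vals <- readBin(raw[(data_start + 1L):length(raw)], "numeric",
                  n = n_par * n_tot, size = 4L, endian = endian)
  m <- matrix(vals, ncol = n_par, byrow = TRUE)
  cn <- vapply(seq_len(n_par),
               function(i) kw[[sprintf("$P%dN", i)]], character(1L))
  df <- as.data.frame(m)
  names(df) <- cn
  list(data = df, keywords = kw)
}

#' Write a per-cell table to CSV
#'
#' CSV mirror of [write_fcs()] for downstream tools that do not read FCS.
#'
#' @param table data.frame, one row per event.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) stop("empty table: nothing to write")
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
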