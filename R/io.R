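# PGM header parsing works on the raw bytes so that P5 pixel data (which
# may contain bytes that look like whitespace) is never touched by a text
# reader. Comments (# ... end of line) may appear between header tokens.
parse_pnm_tokens <- function(bytes, n_tokens) {
  tokens <- character(0)
  i <- 1L
  n <- length(bytes)
  ws <- as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  while (length(tokens) < n_tokens) {
    while (i <= n && bytes[i] %in% ws) i <- i + 1L
    if (i <= n && bytes[i] == as.raw(0x23)) { # '#' comment to end of line
      while (i <= n && !(bytes[i] %in% as.raw(c(0x0a, 0x0d)))) i <- i + 1L
      next
    }
    if (i > n) stop("truncated PGM header")
    start <- i
    while (i <= n && !(bytes[i] %in% ws) && bytes[i] != as.raw(0x23))
      i <- i + 1L
    tokens <- c(tokens, rawToChar(bytes[start:(i - 1L)]))
  }
  list(tokens = tokens, offset = i)
}

#' Read a PGM image (P2 or P5)
#'
#' Parses portable graymap files, ASCII (`P2`) or binary (`P5`), with
#' header comments tolerated. Only 8-bit data (`maxval <= 255`) is
#' supported.
#'
#' @param path Path to the `.pgm` file.
#' @return A numeric matrix (rows = image height) of gray values.
#' @export
read_pgm <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 2) stop("cannot parse PGM: file is empty or truncated")
  magic <- rawToChar(bytes[1:2])
  if (!magic %in% c("P2", "P5"))
    stop("unsupported format: expected PGM magic P2 or P5, got ", magic)
  hdr <- parse_pnm_tokens(bytes[-(1:2)], 3L)
  dims <- as.integer(hdr$tokens)
  if (anyNA(dims)) stop("cannot parse PGM header")
  width <- dims[1]; height <- dims[2]; maxval <- dims[3]
  if (maxval > 255) stop("unsupported format: maxval > 255")
  n_px <- width * height
  if (magic == "P2") {
    txt <- rawToChar(bytes[-(1:(2 + hdr$offset - 1))])
    txt <- gsub("#[^\n]*", "", txt) # comments allowed between samples too
    vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(vals) < n_px || anyNA(vals)) stop("truncated P2 pixel data")
    vals <- vals[seq_len(n_px)]
  } else {
    # exactly one whitespace byte follows the maxval token
    data_start <- 2L + hdr$offset + 1L
    if (data_start + n_px - 1L > length(bytes)) stop("truncated P5 pixel data")
    vals <- as.integer(bytes[seq.int(data_start, length.out = n_px)])
  }
  matrix(vals, nrow = height, byrow = TRUE)
}

#' Write a PGM image (P2 or P5)
#'
#' Gray values are rounded to the nearest integer and clipped to
#' `[0, maxval]` on write, so a write/read round trip is the identity on
#' integer-valued images.
#'
#' @param image Numeric matrix of gray values.
#' @param path Output path.
#' @param format `"P5"` (binary, default) or `"P2"` (ASCII).
#' @param maxval Maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, format = c("P5", "P2"), maxval = 255) {
  format <- match.arg(format)
  image <- as_gray_image(image)
  vals <- as.integer(round(t(image))) # row-major raster order
  vals <- pmin(pmax(vals, 0L), as.integer(maxval))
  header <- sprintf("%s\n%d %d\n%d\n", format, ncol(image), nrow(image),
                    maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  if (format == "P5") {
    writeBin(as.raw(vals), con)
  } else {
    writeBin(charToRaw(paste(vals, collapse = "\n")), con)
    writeBin(charToRaw("\n"), con)
  }
  invisible(path)
}

#' Read a grayscale image (PGM or PNG)
#'
#' Dispatches on the file extension: `.pgm` via [read_pgm()], `.png` via
#' the \pkg{png} package (8-bit grayscale only; values rescaled to
#' `[0, 255]`).
#'
#' @param path Path to the image.
#' @return A numeric matrix of gray values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) {
      if (dim(px)[3] == 2) px <- px[, , 1] # gray + alpha
      else stop("unsupported format: color PNG; expected 8-bit grayscale")
    }
    return(px * 255)
  }
  stop("unsupported image format: .", ext)
}

#' Write a grayscale image (PGM or PNG), chosen by extension
#'
#' @inheritParams write_pgm
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, format = c("P5", "P2")) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm(image, path, format = format))
  if (ext == "png") {
    image <- clip_gray(round(as_gray_image(image))) / 255
    png::writePNG(image, path)
    return(invisible(path))
  }
  stop("unsupported image format: .", ext)
}

#' Map cluster labels to displayable gray levels
#'
#' Label `i` of `c` becomes `round((i - 1) * 255 / (c - 1))`, spreading the
#' labels across the full gray range so cluster maps are viewable PGMs.
#'
#' @param cluster_map Integer matrix of labels in `1..c`.
#' @param c Number of clusters (default: max label).
#' @return Numeric matrix of gray values.
#' @export
labels_to_gray <- function(cluster_map, c = max(cluster_map)) {
  matrix(round((cluster_map - 1) * 255 / (c - 1)), nrow(cluster_map))
}

#' Write all artifacts of a segmentation run
#'
#' Emits the cluster map (labels spread over the gray range) and the
#' cluster-center reconstruction as PGM, the denoised working image when it
#' differs from the input, and a JSON document holding the centers, traces,
#' parameters and seed at full precision. A manifest of written files is
#' returned.
#'
#' @param result A `segmentation_result`.
#' @param out_dir Output directory (created if missing).
#' @param prefix Filename prefix (default the algorithm name).
#' @return Character vector of written paths (the manifest), invisibly.
#' @export
write_result <- function(result, out_dir, prefix = result$algorithm) {
  stopifnot(inherits(result, "segmentation_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(out_dir, paste0(prefix, "_", name))
  manifest <- character(0)
  cmap_path <- p("cluster_map.pgm")
  write_pgm(labels_to_gray(result$cluster_map,
                           length(result$best_centers)), cmap_path)
  manifest <- c(manifest, cmap_path)
  rec_path <- p("reconstruction.pgm")
  write_pgm(result$reconstruction, rec_path)
  manifest <- c(manifest, rec_path)
  if (sum(result$replaced_trace) > 0) {
    den_path <- p("denoised.pgm")
    write_pgm(result$denoised_image, den_path)
    manifest <- c(manifest, den_path)
  }
  json_path <- p("result.json")
  jsonlite::write_json(
    list(algorithm = result$algorithm,
         best_centers = result$best_centers,
         objective = result$objective,
         objective_on_input = result$objective_on_input,
         objective_trace = result$objective_trace,
         replaced_trace = result$replaced_trace,
         n_generations = result$n_generations,
         seed = result$seed,
         params = result$params),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- c(manifest, json_path)
  manifest_path <- file.path(out_dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path)
  invisible(c(manifest, manifest_path))
}
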