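# Plain-file I/O: NRRD volumes (raw/gzip encodings), block corpora with a
# manifest CSV, and feature tables. No binary R serialization anywhere.

#' Read a 3D NRRD volume
#'
#' Supports the subset this package writes: 3-dimensional `raw` or `gzip`
#' encoded data of type double/float/uint8/uint16, little endian. Axis
#' semantics follow the package convention: the first (fastest) file axis is
#' z, then y, then x.
#'
#' @param path file path
#' @return an [image_volume()]
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("read_nrrd: not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ?")[[1]]
    fields[[tolower(kv[1])]] <- kv[2]
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3) stop("read_nrrd: only 3-dimensional volumes supported")
  type <- fields$type
  enc <- fields$encoding
  n <- prod(sizes)
  readfun <- function(con) switch(type,
    "double" = readBin(con, "double", n, size = 8, endian = "little"),
    "float" = readBin(con, "double", n, size = 4, endian = "little"),
    "unsigned char" = , "uint8" = as.numeric(readBin(con, "integer", n, size = 1,
                                                     signed = FALSE)),
    "unsigned short" = , "uint16" = as.numeric(readBin(con, "integer", n, size = 2,
                                                       signed = FALSE,
                                                       endian = "little")),
    stop("read_nrrd: unsupported type ", type))
  if (identical(enc, "raw")) {
    dat <- readfun(con)
  } else if (identical(enc, "gzip") || identical(enc, "gz")) {
    rest <- readBin(con, "raw", n = file.size(path))
    rc <- rawConnection(memDecompress(rest, "gzip"))
    dat <- readfun(rc)
    close(rc)
  } else {
    stop("read_nrrd: unsupported encoding ", enc)
  }
  image_volume(array(dat, dim = sizes))
}

#' Write a 3D volume as NRRD
#'
#' @param volume an [image_volume()] or 3D array
#' @param path output path
#' @param type one of `"double"`, `"float"`, `"uint16"`
#' @param encoding `"raw"` or `"gzip"`
#' @return invisibly, `path`
#' @export
write_nrrd <- function(volume, path, type = "float", encoding = "gzip") {
  if (inherits(volume, "image_volume")) volume <- volume$data
  stopifnot(length(dim(volume)) == 3)
  hdr <- c("NRRD0004",
           paste0("type: ", switch(type, double = "double", float = "float",
                                   uint16 = "unsigned short",
                                   stop("write_nrrd: bad type"))),
           "dimension: 3",
           paste0("sizes: ", paste(dim(volume), collapse = " ")),
           paste0("encoding: ", encoding),
           "endian: little",
           "")
  payload <- switch(type,
    double = writeBin(as.vector(volume), raw(), size = 8, endian = "little"),
    float = writeBin(as.vector(volume), raw(), size = 4, endian = "little"),
    uint16 = writeBin(as.integer(round(volume)), raw(), size = 2,
                      endian = "little"))
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  con <- file(path, "wb")
  writeLines(hdr, con, sep = "\n")
  writeBin(payload, con)
  close(con)
  invisible(path)
}

#' Write a block corpus to a directory
#'
#' One sub-directory per neuron holding `block_<k>.nrrd`, `gold_<k>.swc`,
#' `auto_<k>.swc`, plus a corpus-level `manifest.csv`.
#'
#' @param corpus result of [generate_labeled_corpus()] (or a compatible
#'   list with `blocks` and `manifest`)
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- corpus$manifest
  for (i in seq_along(corpus$blocks)) {
    b <- corpus$blocks[[i]]
    nd <- file.path(dir, b$neuron_id)
    dir.create(nd, showWarnings = FALSE)
    k <- man$block_index[i]
    if (!is.null(b$image)) {
      write_nrrd(b$image, file.path(nd, sprintf("block_%04d.nrrd", k)))
    }
    write_swc(b$gold, file.path(nd, sprintf("gold_%04d.swc", k)))
    write_swc(b$auto, file.path(nd, sprintf("auto_%04d.swc", k)))
  }
  mp <- file.path(dir, "manifest.csv")
  write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a block corpus from a directory
#'
#' @param dir directory produced by [write_corpus()]
#' @return list with `blocks` and `manifest`
#' @export
read_corpus <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop("read_corpus: no manifest.csv in ", dir)
  man <- read.csv(mp, stringsAsFactors = FALSE)
  blocks <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    nd <- file.path(dir, man$neuron_id[i])
    k <- man$block_index[i]
    ip <- file.path(nd, sprintf("block_%04d.nrrd", k))
    img <- if (file.exists(ip)) read_nrrd(ip)$data else NULL
    blocks[[i]] <- structure(
      list(anchor = c(man$anchor_z[i], man$anchor_y[i], man$anchor_x[i]),
           anchor_order_index = man$anchor_order_index[i],
           image = img,
           gold = read_swc(file.path(nd, sprintf("gold_%04d.swc", k))),
           auto = read_swc(file.path(nd, sprintf("auto_%04d.swc", k))),
           label = man$label[i], neuron_id = man$neuron_id[i]),
      class = "tdb_block")
  }
  list(blocks = blocks, manifest = man)
}

#' Similarity and morphometric feature table for a corpus
#'
#' @param blocks list of blocks
#' @return data frame: one row per block with the 10 similarity features
#'   followed by the 32 morphometric features
#' @export
feature_table <- function(blocks) {
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    sf <- similarity_features(b$gold, b$auto)
    lm <- lmeasure_features(b$auto)
    cbind(data.frame(block = i, neuron_id = b$neuron_id,
                     anchor_order_index = b$anchor_order_index,
                     label = b$label),
          as.data.frame(t(c(sf, lm))))
  })
  do.call(rbind, rows)
}

# stable md5 hash of any jsonlite-serializable object
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
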