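#' Read Pascal VOC XML annotations
#'
#' Reads a single VOC XML file or every `*.xml` file in a directory into an
#' [AnnotationSet-class]. VOC stores 1-based inclusive integer pixel
#' coordinates; they are converted to the internal continuous 0-based
#' edges-as-lines convention as `left = xmin - 1`, `top = ymin - 1`,
#' `right = xmax`, `bottom = ymax`, so that `width = right - left` equals the
#' VOC pixel count. Boxes are clipped to the image bounds. An optional
#' `<score>` child of `<object>` (written by [writeVOC()] for detections) is
#' read back as the confidence.
#'
#' @param path a VOC XML file or a directory containing them.
#' @param permissive if `TRUE`, objects with invalid geometry
#'   (`xmax <= xmin` or `ymax <= ymin`) are skipped with a warning; if
#'   `FALSE` (default) they raise an error naming the file and object.
#' @return An [AnnotationSet-class]; the `image_id` of each record is the
#'   file name without extension.
#' @seealso [writeVOC()]
#' @export
readVOC <- function(path, permissive = FALSE) {
  if (length(path) != 1L || !file.exists(path))
    stop(sprintf("path does not exist: %s", path))
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.xml$", full.names = TRUE))
  } else path
  if (length(files) == 0L)
    stop(sprintf("no .xml files found under %s", path))
  imgs <- vector("list", length(files))
  boxl <- vector("list", length(files))
  for (k in seq_along(files)) {
    parsed <- .readVOCFile(files[k], permissive = permissive)
    imgs[[k]] <- parsed$image
    boxl[[k]] <- parsed$boxes
  }
  AnnotationSet(do.call(rbind, boxl), do.call(rbind, imgs))
}

.readVOCFile <- function(file, permissive = FALSE) {
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e) stop(sprintf(
                    "malformed XML in %s: %s", file, conditionMessage(e))))
  image_id <- tools::file_path_sans_ext(basename(file))
  w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  if (is.na(w) || is.na(h) || w <= 0 || h <= 0)
    stop(sprintf("missing or invalid <size> in %s", file))
  objs <- xml2::xml_find_all(doc, ".//object")
  rows <- vector("list", length(objs))
  for (i in seq_along(objs)) {
    o <- objs[[i]]
    name <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    num <- function(tag) as.numeric(
      xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", tag))))
    xmin <- num("xmin"); ymin <- num("ymin")
    xmax <- num("xmax"); ymax <- num("ymax")
    if (anyNA(c(xmin, ymin, xmax, ymax)) || xmax <= xmin || ymax <= ymin) {
      msg <- sprintf("invalid object %d ('%s') in %s: bndbox (%s, %s, %s, %s)",
                     i, name, file, xmin, ymin, xmax, ymax)
      if (permissive) { warning(msg); rows[i] <- list(NULL); next }
      stop(msg)
    }
    sc_node <- xml2::xml_find_first(o, "./score")
    score <- if (length(sc_node) == 0L || inherits(sc_node, "xml_missing"))
      NA_real_ else as.numeric(xml2::xml_text(sc_node))
    rows[[i]] <- data.frame(
      image_id = image_id, label = name, score = score,
      left = max(xmin - 1, 0), top = max(ymin - 1, 0),
      right = min(xmax, w), bottom = min(ymax, h),
      stringsAsFactors = FALSE)
  }
  list(image = data.frame(image_id = image_id, width = w, height = h,
                          stringsAsFactors = FALSE),
       boxes = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Write Pascal VOC XML annotations
#'
#' Writes one `<image_id>.xml` file per image of the set, converting internal
#' continuous coordinates back to 1-based inclusive VOC integers (the inverse
#' of the [readVOC()] conversion, with rounding to the nearest integer, so a
#' read/write round trip moves no boundary by more than 0.5 px). Boxes are
#' clipped to image bounds first. Scored boxes gain a `<score>` child element.
#'
#' @param x An [AnnotationSet-class].
#' @param path output directory (created if absent).
#' @return Invisibly, the number of files written.
#' @export
writeVOC <- function(x, path) {
  stopifnot(is(x, "AnnotationSet"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory %s", path))
  }
  x <- clipBoxes(x)
  img <- imageInfo(x)
  b <- annotationBoxes(x)
  for (k in seq_len(nrow(img))) {
    id <- img$image_id[k]
    bi <- b[b$image_id == id, , drop = FALSE]
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", paste0(id, ".jpg"))
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width", format(img$width[k]))
    xml2::xml_add_child(size, "height", format(img$height[k]))
    xml2::xml_add_child(size, "depth", "3")
    for (i in seq_len(nrow(bi))) {
      o <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(o, "name", bi$label[i])
      if (!is.na(bi$score[i]))
        xml2::xml_add_child(o, "score", sprintf("%.6f", bi$score[i]))
      bb <- xml2::xml_add_child(o, "bndbox")
      xmin <- round(bi$left[i]) + 1
      ymin <- round(bi$top[i]) + 1
      xmax <- max(round(bi$right[i]), xmin)
      ymax <- max(round(bi$bottom[i]), ymin)
      xml2::xml_add_child(bb, "xmin", format(xmin))
      xml2::xml_add_child(bb, "ymin", format(ymin))
      xml2::xml_add_child(bb, "xmax", format(xmax))
      xml2::xml_add_child(bb, "ymax", format(ymax))
    }
    xml2::write_xml(doc, file.path(path, paste0(id, ".xml")))
  }
  invisible(nrow(img))
}

#' Read scored detections from JSON
#'
#' The JSON dialect is a flat array of objects with fields `image_id`,
#' `label`, `score`, `left`, `top`, `right`, `bottom` in internal continuous
#' coordinates, plus optional `width`/`height` of the owning image (written
#' by [writeDetections()]). When image dimensions are absent from the file
#' they must be supplied through `images`.
#'
#' @param path JSON file.
#' @param images optional image table (`image_id`, `width`, `height`) or an
#'   [AnnotationSet-class] to take it from.
#' @return An [AnnotationSet-class] of scored boxes.
#' @export
readDetections <- function(path, images = NULL) {
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path))
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is(images, "AnnotationSet")) images <- imageInfo(images)
  if (length(rec) == 0L || NROW(rec) == 0L) {
    if (is.null(images)) stop("empty detection file and no `images` supplied")
    return(AnnotationSet(emptyBoxFrame(), images))
  }
  need <- c("image_id", "label", "score", "left", "top", "right", "bottom")
  if (!all(need %in% names(rec)))
    stop(sprintf("detection JSON %s lacks field(s): %s", path,
                 paste(setdiff(need, names(rec)), collapse = ", ")))
  if (is.null(images)) {
    if (!all(c("width", "height") %in% names(rec)))
      stop("detection JSON has no width/height fields; supply `images`")
    images <- unique(rec[, c("image_id", "width", "height")])
  } else {
    extra <- setdiff(unique(rec$image_id), images$image_id)
    if (length(extra))
      stop(sprintf("detections reference unknown image(s): %s",
                   paste(utils::head(extra, 5L), collapse = ", ")))
  }
  AnnotationSet(rec[, need], images)
}

#' Write scored detections to JSON
#'
#' @param x An [AnnotationSet-class]; every box must carry a score.
#' @param path output JSON file.
#' @return Invisibly, the number of boxes written.
#' @seealso [readDetections()]
#' @export
writeDetections <- function(x, path) {
  stopifnot(is(x, "AnnotationSet"))
  b <- annotationBoxes(x)
  if (nrow(b) && anyNA(b$score))
    stop("all boxes must be scored to be written as detections")
  d <- .boxImageDims(b, imageInfo(x))
  b$width <- d$width
  b$height <- d$height
  jsonlite::write_json(b, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(nrow(b))
}
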