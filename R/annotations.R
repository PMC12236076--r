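# Annotation interchange: YOLO text records (class id + normalized
# center-form box per line) and VOC-style XML (class name words + pixel
# corner coordinates). Records round-trip between the two within one pixel.

#' The five weed classes, in label-id order (ids 0-4)
#' @export
weed_classes <- function() {
  c("beggartick", "crabgrass", "galinsoga_quadriradiata",
    "goosegrass", "tropic_ageratum_herb")
}

#' Build an annotation record set
#'
#' @param class_id integer vector of class ids.
#' @param cx,cy,w,h normalized center-form box coordinates in `[0, 1]`.
#' @param image optional image identifier.
#' @return data frame with columns class_id, cx, cy, w, h (and image).
#' @export
annotation_records <- function(class_id, cx, cy, w, h, image = NA_character_) {
  rec <- data.frame(class_id = as.integer(class_id),
                    cx = cx, cy = cy, w = w, h = h,
                    image = image, stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

validate_records <- function(rec, n_classes = 5L, tol = 1e-6) {
  if (nrow(rec) == 0L) return(invisible(rec))
  ok_cls <- rec$class_id >= 0L & rec$class_id < n_classes
  if (!all(ok_cls))
    stop("annotation records: class id out of range 0..", n_classes - 1L)
  x1 <- rec$cx - rec$w / 2; x2 <- rec$cx + rec$w / 2
  y1 <- rec$cy - rec$h / 2; y2 <- rec$cy + rec$h / 2
  inside <- x1 >= -tol & y1 >= -tol & x2 <= 1 + tol & y2 <= 1 + tol &
    rec$w >= 0 & rec$h >= 0
  if (!all(inside))
    stop("annotation records: box not fully inside [0,1] (record ",
         which(!inside)[1], ")")
  invisible(rec)
}

#' Read YOLO-format annotations from a text file
#'
#' One record per line: `class cx cy w h`, whitespace separated,
#' coordinates normalized to `[0, 1]`.
#' @param path file path.
#' @param image image id stored with the records (default: file stem).
#' @export
read_yolo_txt <- function(path, image = NULL) {
  if (is.null(image)) image <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(annotation_records(integer(0), numeric(0), numeric(0),
                              numeric(0), numeric(0)))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    vals <- suppressWarnings(as.numeric(p))
    if (length(p) != 5L || anyNA(vals))
      stop("malformed YOLO annotation at line ", i, " of ", path,
           ": expected 'class cx cy w h'")
  }
  m <- do.call(rbind, lapply(parts, as.numeric))
  annotation_records(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], image = image)
}

#' Write annotations as YOLO text
#' @param records annotation data frame (see [annotation_records()]).
#' @param path output file; one `class cx cy w h` line per record.
#' @param digits decimal places for the coordinates.
#' @export
write_yolo_txt <- function(records, path, digits = 6L) {
  validate_records(records)
  lines <- sprintf(paste0("%d %.", digits, "f %.", digits, "f %.",
                          digits, "f %.", digits, "f"),
                   records$class_id, records$cx, records$cy,
                   records$w, records$h)
  writeLines(lines, path)
  invisible(path)
}

#' Convert annotation records to a VOC-style XML document
#'
#' Class ids become class-name words; boxes become 0-based pixel corner
#' coordinates (`xmin`, `ymin`) = top-left, (`xmax`, `ymax`) = bottom-right,
#' rounded to whole pixels.
#'
#' @param records annotation data frame.
#' @param image_size `c(width, height)` in pixels.
#' @param image_name file name stored in the header.
#' @param path optional path; when given, the document is written there.
#' @return an `xml2::xml_document`.
#' @export
to_voc_xml <- function(records, image_size, image_name = "image.png",
                       path = NULL) {
  validate_records(records)
  classes <- weed_classes()
  W <- image_size[1]; H <- image_size[2]
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", image_name)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(W))
  xml2::xml_add_child(size, "height", as.character(H))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(records))) {
    cid <- records$class_id[i]
    if (cid < 0L || cid >= length(classes))
      stop("to_voc_xml: unknown class id ", cid)
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", classes[cid + 1L])
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(round((records$cx[i] - records$w[i] / 2) * W)))
    xml2::xml_add_child(bb, "ymin", as.character(round((records$cy[i] - records$h[i] / 2) * H)))
    xml2::xml_add_child(bb, "xmax", as.character(round((records$cx[i] + records$w[i] / 2) * W)))
    xml2::xml_add_child(bb, "ymax", as.character(round((records$cy[i] + records$h[i] / 2) * H)))
  }
  if (!is.null(path)) xml2::write_xml(doc, path)
  doc
}

#' Read a VOC-style XML annotation back into records
#' @param x path to an XML file or an `xml2::xml_document`.
#' @export
from_voc_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  classes <- weed_classes()
  W <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  H <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0L)
    return(annotation_records(integer(0), numeric(0), numeric(0),
                              numeric(0), numeric(0)))
  rows <- lapply(objs, function(o) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    cid <- match(nm, classes) - 1L
    if (is.na(cid)) stop("from_voc_xml: unknown class name '", nm, "'")
    g <- function(tag) as.numeric(xml2::xml_text(
      xml2::xml_find_first(o, paste0("./bndbox/", tag))))
    x1 <- g("xmin"); y1 <- g("ymin"); x2 <- g("xmax"); y2 <- g("ymax")
    c(cid, (x1 + x2) / 2 / W, (y1 + y2) / 2 / H, (x2 - x1) / W, (y2 - y1) / H)
  })
  m <- do.call(rbind, rows)
  annotation_records(m[, 1], pmin(pmax(m[, 2], 0), 1), pmin(pmax(m[, 3], 0), 1),
                     pmin(m[, 4], 1), pmin(m[, 5], 1),
                     image = sub("\\.[^.]*$", "",
                                 xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))))
}
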