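# small in-code fixtures shared by the unit tests

one_image <- function(id = "img", size = 640) {
  data.frame(image_id = id, width = size, height = size,
             stringsAsFactors = FALSE)
}

box_row <- function(left, top, right, bottom, label = "gray_mold",
                    score = NA_real_, image_id = "img") {
  data.frame(image_id = image_id, label = label, score = score,
             left = left, top = top, right = right, bottom = bottom,
             stringsAsFactors = FALSE)
}

toy_set <- function(..., images = one_image()) {
  AnnotationSet(do.call(rbind, list(...)), images)
}

# a VOC XML file written by hand (1-based inclusive integer coordinates)
write_voc_fixture <- function(dir, id, objects, size = 640) {
  lines <- c("<annotation>",
             sprintf("  <filename>%s.jpg</filename>", id),
             "  <size>",
             sprintf("    <width>%d</width>", size),
             sprintf("    <height>%d</height>", size),
             "    <depth>3</depth>",
             "  </size>")
  for (o in objects) {
    lines <- c(lines, "  <object>",
               sprintf("    <name>%s</name>", o$name),
               "    <bndbox>",
               sprintf("      <xmin>%s</xmin>", o$xmin),
               sprintf("      <ymin>%s</ymin>", o$ymin),
               sprintf("      <xmax>%s</xmax>", o$xmax),
               sprintf("      <ymax>%s</ymax>", o$ymax),
               "    </bndbox>",
               "  </object>")
  }
  lines <- c(lines, "</annotation>")
  writeLines(lines, file.path(dir, paste0(id, ".xml")))
}
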