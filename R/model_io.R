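#' Write a CRM model to a structured text file
#'
#' All free parameters, the PWMs and the background tables are written as
#' YAML, so a trained model can be inspected, versioned and reloaded with
#' [read_crm_model].
#'
#' @param model A [crm_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crm_model <- function(model, path) {
  fw <- model$motifs[seq_len(model$K)]
  obj <- list(
    p_r = model$p_r, q0 = model$q0, h = model$h,
    z_threshold = model$z_threshold, E_threshold = model$E_threshold,
    q = as.numeric(model$q),
    corr = lapply(model$corr, function(ri)
      if (length(ri) == 0L) list() else as.list(ri)),
    motifs = lapply(fw, function(p) list(
      id = p$id, tf_label = p$tf_label,
      matrix = lapply(seq_len(p$length), function(j)
        as.numeric(p$matrix[, j])))),
    theta0 = serialize_background(model$theta0),
    theta1 = serialize_background(model$theta1)
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

serialize_background <- function(bg) {
  list(order = bg$order,
       tables = lapply(bg$tables, function(tab)
         lapply(seq_len(nrow(tab)), function(r) as.numeric(tab[r, ]))))
}

deserialize_background <- function(obj) {
  tables <- lapply(obj$tables, function(tab) {
    m <- do.call(rbind, lapply(tab, as.numeric))
    m / rowSums(m)  # absorb round-off from the text representation
  })
  markov_background(obj$order, tables)
}

#' Read a CRM model written by [write_crm_model]
#'
#' @param path Path to the model file.
#' @return A [crm_model].
#' @export
read_crm_model <- function(path) {
  obj <- yaml::read_yaml(path)
  pwms <- lapply(obj$motifs, function(mo) {
    m <- do.call(cbind, lapply(mo$matrix, as.numeric))
    m <- sweep(m, 2L, colSums(m), "/")
    pwm(mo$id, m, tf_label = mo$tf_label)
  })
  corr <- lapply(obj$corr, function(ri) {
    if (length(ri) == 0L) return(numeric(0))
    v <- vapply(ri, as.numeric, 0)
    names(v) <- names(ri)
    v
  })
  q <- as.numeric(obj$q)
  crm_model(pwms,
            theta0 = deserialize_background(obj$theta0),
            theta1 = deserialize_background(obj$theta1),
            p_r = obj$p_r, q0 = obj$q0, h = obj$h,
            q = q / sum(q), corr = corr,
            z_threshold = obj$z_threshold, E_threshold = obj$E_threshold)
}
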