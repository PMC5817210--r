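#' @keywords internal
"_PACKAGE"

# Published per-variable summary of the virtual terfenadine DDI trial data set:
# min, first quartile, median, mean, third quartile, max on the raw scale for
# the 48 model inputs plus the dQTc output. These knots are the sole
# calibration source for the virtual-population generator and the 0.1-0.9
# scaler. Transcribed verbatim, including the Gut_CYP2C9 row whose printed
# minimum (8210) exceeds its printed first quartile (1430); see
# quantile_sampler(repair = TRUE) for how the generator handles that row.
.reference_summary <- local({
  txt <- "
num|name|units|vmin|q25|median|mean|q75|vmax
1|CYP1A2|pmol/mg protein (liver)|0|0|0|695159|0|11963910
2|CYP2A6|pmol/mg protein (liver)|0|0|0|0|0|0
3|CYP2B6|pmol/mg protein (liver)|0|0|0|86155|0|9129915
4|CYP2C8|pmol/mg protein (liver)|0|0|0|0|0|0
5|CYP2C9|pmol/mg protein (liver)|0|0|0|347459|0|16469809
6|CYP2C18|pmol/mg protein (liver)|0|0|0|0|0|0
7|CYP2C19|pmol/mg protein (liver)|0|0|0|179400|0|5511004
8|CYP2D6|pmol/mg protein (liver)|0|252231|399478|506695|676312|2185456
9|CYP2E1|pmol/mg protein (liver)|0|0|0|0|0|0
10|CYP2J2|pmol/mg protein (liver)|0|0|0|0|0|0
11|CYP3A4|pmol/mg protein (liver)|1552693|5716140|8459929|9833766|12016781|32307836
12|CYP3A5|pmol/mg protein (liver)|0|0|0|272853|0|13728653
13|CYP3A7|pmol/mg protein (liver)|0|0|0|0|0|0
14|Gut_CYP2C9|nmol/small intestine|8210|1430|10037.216|10089.122|10148.391|10388.032
15|Gut_CYP2C19|nmol/small intestine|0|0|0|299|0|7330
16|Gut_CYP2D6|nmol/small intestine|0|484.7|674.4|818.4|994.5|3156
17|Gut_CYP2J2|nmol/small intestine|0|0|0|0|0|0
18|Gut_CYP3A4|nmol/small intestine|11214|35540|55975|62911|80376|217447
19|Gut_CYP3A5|nmol/small intestine|0|0|0|807.2|0|55106.1
20|Sex_Code|male=0/female=1|0|1|1|0.7718|1|1
21|Age|years|19|25|28|28.39|32|52
22|Weight|kg|44.52|69.43|78.31|79.04|89.17|127
23|Height|cm|149.4|168.6|174.3|173.6|179.7|200.5
24|BSA|m^2|1.422|1.802|1.937|1.929|2.048|2.432
25|Brain_Weight|g|1040|1230|1354|1388|1524|2057
26|Kidney_Weight|g|164.1|269.1|325|329.1|382.6|752
27|Liver_Weight|g|1052|1544|1700|1740|1938|2699
28|BMI|kg/m^2|16.13|22.87|26.22|26.19|28.8|45.31
29|Cardiac_Output|L/h|249.7|315.1|339.4|337.5|357.2|424.5
30|Haematocrit|%|32.12|38.99|41.73|41.46|43.68|51.05
31|HSA|g/L|35.11|42.88|45.74|45.75|48.57|58.08
32|AGP|g/L|0.3971|0.7137|0.8035|0.7982|0.8851|1.207
33|Serum_Creatinine|umol/L|33.64|62.09|73.26|72.61|81.2|122.95
34|GFR|mL/min/1.73m^2|70.97|112.12|129.74|133.34|153.5|243.16
35|Renal_Function|ratio|0.59|0.92|1.079|1.089|1.271|1.87
36|Cardiomyocyte_area|um^2|652.5|1384.3|1701.1|1824.4|2146.8|5353.7
37|Cardiomyocyte_volume|um^3|1852|4494|5630|6217|7346|20339
38|Sarcoplasmic_reticulum_volume|um^3|111.1|269.6|337.8|373|440.7|1220.3
39|Capacitance|pF|17.33|36.77|45.18|48.46|57.02|142.2
40|String_length|cm|0.8772|1.1814|1.293|1.2878|1.4064|1.8619
41|K|mM|3.053|4.079|4.268|4.261|4.451|5.363
42|Na|mM|135.1|139.6|140.4|140.3|141.1|143.3
43|Ca2|mM|2.007|2.237|2.388|2.394|2.546|2.789
44|IKr_inhibition|fraction|0.0047|0.0484|0.1172|0.2378|0.3841|1
45|IKs_inhibition|fraction|0|0.0001|0.0001|0.0002684|0.0003|0.008
46|INa_inhibition|fraction|0|0.0003|0.0007|0.001493|0.0016|0.0353
47|ICa_inhibition|fraction|0|0.0009|0.0022|0.01782|0.0061|0.5217
48|Stimulation_Period|ms|432|735|825|836.1|925|1570
49|dQTc|ms|-15.707|1.713|6.591|10.572|14.69|78.142
"
  df <- utils::read.table(text = txt, sep = "|", header = TRUE,
                          stringsAsFactors = FALSE)
  knots <- c("vmin", "q25", "median", "q75", "vmax")
  df$vclass <- "continuous"
  df$vclass[apply(df[, c(knots, "mean")] == 0, 1, all)] <- "constant"
  df$vclass[df$name == "Sex_Code"] <- "binary"
  df$role <- ifelse(df$name == "dQTc", "output", "input")
  df
})

# Trial arms: the victim drug alone plus the seven interacting metabolic
# inhibitors. Terfenadine-alone serves as the eighth cross-validation group.
.trial_arms <- c("terfenadine", "clarithromycin", "erythromycin",
                 "itraconazole", "ketoconazole", "fluconazole",
                 "fluoxetine", "paroxetine")

#' Published per-variable summary specifications
#'
#' Returns the packaged summary-statistic specification for every covariate of
#' the virtual terfenadine drug-drug-interaction trials: 48 input variables
#' (CYP abundances, demographics, cardiac geometry, plasma electrolytes,
#' fractional ion-channel inhibitions, stimulation period) plus the `dQTc`
#' output. Each row carries the published minimum, quartiles, median, mean and
#' maximum on the raw scale, a units string, and a variable class:
#' `"continuous"`, `"constant"` (identically zero in the source trials) or
#' `"binary"` (the sex code).
#'
#' These specifications drive [quantile_sampler()] and [fit_scaler()].
#'
#' @param role `"input"`, `"output"` or `"all"` (default) — which rows to
#'   return.
#' @return A data frame with columns `num`, `name`, `units`, `vmin`, `q25`,
#'   `median`, `mean`, `q75`, `vmax`, `vclass`, `role`.
#' @examples
#' specs <- reference_specs()
#' specs[specs$name == "K", ]
#' @export
reference_specs <- function(role = c("all", "input", "output")) {
  role <- match.arg(role)
  df <- .reference_summary
  if (role != "all") df <- df[df$role == role, ]
  rownames(df) <- NULL
  df
}

#' Trial arm labels
#'
#' The eight treatment arms of the simulated clinical studies: terfenadine
#' alone and terfenadine with each of seven metabolic inhibitors.
#'
#' @return Character vector of length 8.
#' @export
trial_arms <- function() .trial_arms

#' Default virtual-trial design
#'
#' The design of the source virtual trials: 63 patients, 8 treatment arms and
#' 10,360 records in total. The published summary gives no per-patient or
#' per-arm breakdown, so records are allocated deterministically: each patient
#' receives `floor(10360 / 63)` records with the remainder going to the lowest
#' patient ids, and each patient's records are spread near-equally over the 8
#' arms (remainder to the first arms in label order).
#'
#' @param n_patients Number of virtual patients.
#' @param total_records Total record count across all patients and arms.
#' @param arms Character vector of arm labels.
#' @return An object of class `trial_design`: a list with `arms`,
#'   `n_patients`, `total_records` and `allocation` (a data frame with one row
#'   per patient x arm giving `n_records`).
#' @examples
#' d <- default_design()
#' d$total_records
#' @export
default_design <- function(n_patients = 63L, total_records = 10360L,
                           arms = trial_arms()) {
  n_patients <- as.integer(n_patients)
  total_records <- as.integer(total_records)
  if (n_patients < 1L || total_records < n_patients)
    stop("design needs at least one record per patient")
  per_patient <- rep(total_records %/% n_patients, n_patients)
  rem <- total_records %% n_patients
  if (rem > 0L) per_patient[seq_len(rem)] <- per_patient[seq_len(rem)] + 1L
  n_arms <- length(arms)
  alloc <- do.call(rbind, lapply(seq_len(n_patients), function(p) {
    base <- rep(per_patient[p] %/% n_arms, n_arms)
    r <- per_patient[p] %% n_arms
    if (r > 0L) base[seq_len(r)] <- base[seq_len(r)] + 1L
    data.frame(patient_id = p, arm = arms, n_records = base,
               stringsAsFactors = FALSE)
  }))
  alloc <- alloc[alloc$n_records > 0L, ]
  rownames(alloc) <- NULL
  structure(list(arms = arms, n_patients = n_patients,
                 total_records = total_records, allocation = alloc),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Virtual trial design: ", x$n_patients, " patients, ",
      length(x$arms), " arms, ", x$total_records, " records\n", sep = "")
  invisible(x)
}

validate_design <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  if (sum(design$allocation$n_records) != design$total_records)
    stop("allocation does not sum to total_records")
  if (!all(seq_len(design$n_patients) %in% design$allocation$patient_id))
    stop("every patient must appear in at least one arm")
  invisible(design)
}
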