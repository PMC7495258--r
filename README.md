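# pumpconcord

Reconciling smart infusion pump records with EHR medication orders to
detect medication administration discrepancies in continuous infusions.

## The problem

Smart infusion pumps log every programming event — which patient, which
medication, what dose or rate, at what minute — but in most hospitals the
pumps are not integrated with the EHR, so nothing ties a pump record (SPR)
to the medication order it executes. The EHR side has its own record of
administration, the MAR, which is hand-entered and error-prone in its own
way. `pumpconcord` implements the computational pipeline for putting the
two sides together for high-risk continuous infusions (vasopressors,
narcotics, TPN, lipids) in an intensive-care setting:

1. **Validity screening.** Pump patient IDs are hand-keyed. Each SPR is
   placed in a 2×2 quadrant (valid patient ID × medication name selected
   from the drug library), and invalid IDs are categorized into nine
   failure modes (date of birth typed instead of ID, patient name,
   encounter ID, missing/extra digits, invalid letters, expired ID after a
   chart merge, one-keystroke typo, random number) under a fixed
   specific-before-generic precedence.
2. **Alignment.** Usable started/restarted SPRs are grouped with orders
   and MARs by (patient, medication) and each SPR is linked to the closest
   order with activity (placement, modification, or MAR documentation)
   within 24 h of the administration.
3. **Discrepancy detection.** Every MAR and linked SPR is compared with
   the prescribed dose/rate in force at its timestamp. A matching order
   placed within a 30-minute grace window legitimizes the administration
   (verbal order being transcribed); a matching order arriving later than
   that is a *documentation* discrepancy with magnitude 0%. The magnitude
   of discrepancy (MoD) for dose mismatches is

   MoD = (administered − prescribed) / prescribed × 100%,

   binned into ten reporting intervals from <−50% to >100% (MoD > 100% is
   a *substantial overdose*).
4. **Concordance.** Each order's timeline is segmented into event blocks
   at order initiations/modifications; blocks are classified as having
   no / MAR-only / SPR-only / both discrepancies, and Cohen's kappa
   κ = (pₒ − pₑ)/(1 − pₑ) over the block-level 2×2 table measures how far
   the two sources flag the same problems.

Because real pump/EHR extracts are protected, the package ships a
synthetic cohort generator (`generate_cohort()`) that emulates the paired
streams — order sequences with dose titrations, MAR/SPR documentation
cadences, and every corruption channel above — while recording each
planted error in a ground-truth ledger, so the whole pipeline is testable
end to end (`evaluate_against_ledger()`).

## Worked example

```r
library(pumpconcord)

cfg <- cohort_config(n_patients = 40, seed = 5)
err <- error_mixture(p_mar_discrepancy = 0.05, p_spr_discrepancy = 0.05,
                     p_late_order = 0.05)
cohort <- generate_cohort(cfg, err)
report <- run_pipeline(cohort)

report$rates[report$rates$medication == "Overall", ]
#> # A tibble: 1 x 7
#>   medication n_mar mar_disc mar_rate n_spr spr_disc spr_rate
#>   <chr>      <int>    <int>    <dbl> <int>    <int>    <dbl>
#> 1 Overall      620       42      6.8  1146       35      3.1

evaluate_against_ledger(report, cohort$ledger)[1:3]
#> $sensitivity
#> [1] 1
#> $precision
#> [1] 1
#> $max_mod_error
#> [1] 0
```

620 MARs and 1146 linked pump records were evaluated; the injected
per-block error rates of 5% produce overall record-level discrepancy
rates of 6.8% (MAR) and 3.1% (SPR), and every planted error — dose
corruptions and late-order documentation discrepancies alike — is
recovered with no false positives and exact magnitude recovery.

The numbered drivers under `analysis/` run the same stages as a
narrative workflow at study scale and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R     # streams + ground-truth ledger
Rscript analysis/02_screen.R      # validity quadrants, invalid-ID table
Rscript analysis/03_align_detect.R  # linkage, discrepancies, MoD bins
Rscript analysis/04_concordance.R   # event blocks, kappa
Rscript analysis/05_evaluate.R      # recovery against the ledger
```

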