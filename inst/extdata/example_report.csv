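episode_id,report_text
ABC1234,"CLINICAL HISTORY: A 67 YEAR OLD MALE PATIENT WITH A PSA OF 7.9 UG/L. PROSTATE BIOPSIES HAVE BEEN DONE. MACROSCOPY: SIXTEEN CORES OF TISSUE, THE LONGEST MEASURING 15MM AND THE SHORTEST MEASURING 7MM. PATHOLOGICAL DIAGNOSIS: PROSTATE CORE BIOPSIES SHOWING THE FOLLOWING FEATURES: AN INVASIVE PROSTATIC ADENOCARCINOMA. TWO CORES ARE INVOLVED AND < 5% OF THE TISSUE. GLEASON 4, 3. PERINEURAL AND LYMPHOVACULAR INVASION ARE NOT IDENTIFIED. IMMUNOHISTOCHEMISTRY: IN THE PRESENCE OF ADEQUATE POSITIVE CONTROLS, IMMUNOHISTOCHEMICAL STAINS HAVE BEEN DONE AND THE FOLLOWING RESULTS OBTAINED: P63 AND CK5/6: BASAL CELLS ARE NOT DEMONSTRATED IN THE ATYPICAL GLANDS"
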