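# SYNTHETIC reference landmarks for motif anchoring.
# These sequences are generated stand-ins for yeast totivirus CP/RdRp
# references (which are not redistributed); each row gives the planted
# position of a landmark in the synthetic reference.
ref_id	motif_name	start	end	consensus	note
totivirus_CP_ref_synthetic	cap_snatching_His	154	154	H	synthetic stand-in; planted landmark, not a deposited sequence
totivirus_RdRp_ref_synthetic	motif_I	330	335	KDEKLS	synthetic stand-in; planted landmark, not a deposited sequence
totivirus_RdRp_ref_synthetic	motif_II	380	384	GIPSG	synthetic stand-in; planted landmark, not a deposited sequence
totivirus_RdRp_ref_synthetic	motif_III	425	429	WDWSV	synthetic stand-in; planted landmark, not a deposited sequence
totivirus_RdRp_ref_synthetic	motif_IV	470	475	TTNLYT	synthetic stand-in; planted landmark, not a deposited sequence
totivirus_RdRp_ref_synthetic	motif_V	530	535	YGLLMS	synthetic stand-in; planted landmark, not a deposited sequence
totivirus_RdRp_ref_synthetic	motif_VI_GDD	611	613	GDD	synthetic stand-in; planted landmark, not a deposited sequence
totivirus_RdRp_ref_synthetic	motif_VII	660	665	QRGIRA	synthetic stand-in; planted landmark, not a deposited sequence
totivirus_RdRp_ref_synthetic	motif_VIII	705	710	HTGIFF	synthetic stand-in; planted landmark, not a deposited sequence
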