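>totivirus_CP_ref_synthetic synthetic stand-in; cap-snatching His planted at position 154
KVSRALWPCDLGGDLTMMFTHIDPEFHHTNLRAKFMRWESVCWWWGMHAMYPVQFRMHWD
YLRNNHTITQTDRCICFRRQFKQPVKICCPDTVGWVYHKDLPYAFVMEHETYTCVTPGDE
VLCVFWWHMEIYFPITRCIIARFMRVWYYGLRFHWCFMPMNRQYGTEAAMQFSEIALAQR
LDSLLEIALNWASLEEDIIATNNISDEHMMQEAKSCMYYRHMQTFDVIDFGNSSMLGINF
TCPTCGTWWCIQDLKQSTENTFQATCDWIWISTNYKRNDEKWTHTMIPILNCCVCERVYL
RPCMNEKTEVNMMTHRIEWQKAWLICIVFFEMSFLASPVWFYKMADDYLCLNQANQYFCA
QTFVIGSNIGWYQFMPDKLMHIGCHEQSEWSMWWKKIVHQFLPPTCMQADVPGMYVLWMN
ATTDKMATIKQLKTNMVFHFNVCHLSYPPAQKCKVLNQMARWSIRVTESTATTLDMTLNK
HAQNGSVFGGSFYLVMEHQLKWEQNMWIYECDIMWAPIIPYRLDWIQDIRKTHHMLTGHD
DTVPFSVARIALSAEADFPSFMVKGNPYDEPQDGIYDENDKMRYLVIDKNRNFLRISLGD
HDGNMEYCFYDAYKDPRMKPKSTNSKNIYTFMSKMKTAGKHLTWGRSFDKEIPARFHPFD
GKIDGSPHNPQYFMPSTYFE
>totivirus_RdRp_ref_synthetic synthetic stand-in; eight planted motif blocks, GDD in motif VI
ILWYKKFWDLVTLHFLYCWNTSATTSHNGCDSGLYYMPNPWECQSHMDIWPVDYCLTEVP
TRKMGLCICACPFVSEWLYLNNERKETPIMHTRKKSYGPREAHFPATERNEGGQYDHQYD
WCALGCKEYKTDMYMIYEGQNRWPPFVFDHICGWQKGKCMPEQHEWEGFAALRHNFRQST
MGIDDIEFMKSFECQNCTHPVHIWCAYQCLHRMNFADWCVMSTHAWTRDFVMVVRLNWVH
DEGGQYTTKMMLGGQLTYSICQKKMSKPRPFCIQYWIKPPGPAEKGAFMNNFKIGKHPME
NKVAQQAMKLERDQLQLFTHLFISYFHVFKDEKLSPLHGPYRFHHGEPSDNLVFMEARAF
CERVCVDLCPDWVRKMQAFGIPSGMGRYLWYNWPLIEIKMVWMTRHNPMECHVQLYKDSF
QPLNWDWSVTCPERQLSDNRTVYTEKLSYHFTMATEMLPGDICPPIDRRTTNLYTNSVWA
VICYFEATKPNEFTGKCPRYVWLGVTMEESPAQFIVSCAVHFWIDQTPNYGLLMSEPRNI
IGIRCHVCTEIAPQTNYINFYEWPQFPCHPRMKDSESDFQNVSANLPYYHGMWPEADSWQ
TACALVYMKSGDDSLDRAGVANISPYYTNKTEDHYMVHCPTTITWAHWGMKSKWLGKPRQ
RGIRAYAPDYNWSQMDRNRGNAVTKNVRCMDHDPSEQSQCTRICHTGIFFCDCNEEWTIW
FYACPEPVTPWAPTWCDCTTGLVMMFAWYVFCYTYYKLLHCQCHKPSQNICESHERFAHC
MMHAANCQPYGWKWKADTCAVTQPVYDALHEFSKQFIQWSHGCACNAHDQHKKQYMHVHG
LSYLTKQQWDFKKSWEFYPV
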