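>ERF_ref1 subfamily=ERF synthetic reference domain
SGYGGVRKRPGGKFAAEIRDPWKKTRVWLGTFDTAEEAARAYDVAAREFRGPKAKTNF
>ERF_ref2 subfamily=ERF synthetic reference domain
SGYGGVRKRPGGKFAAEIRDPWKKTRVWLGTFKTAEEAARAYDVAAREFRGPKAKTNQ
>DREB_ref1 subfamily=DREB synthetic reference domain
SGWGGVGKRPQGKFEAEIEDPWHKTRLWLGWFDTYEEAYRAYCVAAFEFRVPKAMTNF
>DREB_ref2 subfamily=DREB synthetic reference domain
SGWGGVGKRPQGKSEAEIEDPWHKTRLWLFWFDTYEEAYRAYCVAAFEFRVPKAMTNF
>DRF_ref1 subfamily=DRF synthetic reference domain
SGYGRVRKYPGGTFAAVIRDGWKKHRVWTGTFQTAEAAARQYDVHAREWRGPWAKTLF
>DRF_ref2 subfamily=DRF synthetic reference domain
SGYGRVRKYPGGTFAAVIRDGWRKHRVWTGWFQTAEAARRQYDVHAREWRGPWAKTLF
>SOLOIST_ref1 subfamily=SOLOIST synthetic reference domain
SVYGGVLKEPGWKFAICIKDLKERTRVWLGTFDTLEEAARAADVYMGENRRDKACTNF
>SOLOIST_ref2 subfamily=SOLOIST synthetic reference domain
SVCGGVLKEPGWKFAICIKDLKERTRVWLGTFDTLEEAARAADVYMGENRRDKACTNF
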