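>AP2_syn01 synthetic AP2-domain alignment member
SGYGSVRKRPGGKFAAEIRDPWKKTRVWLGTFLTAEEAARAYDVAAREFRGEKAKTNF
>AP2_syn02 synthetic AP2-domain alignment member
SGYGGVRKRVGGKFAAECRDPWKKTRVWLGTFDTAENAARAYDVAAREQRGPKAKTNF
>AP2_syn03 synthetic AP2-domain alignment member
SGYGGVRKRPGGKFAAEIRDPWKVSRVWLGTFDTAEEAANAYDVAAREFRGPKAKTNF
>AP2_syn04 synthetic AP2-domain alignment member
SGYGGSRKRPGGKFAAEIRDPWKKTRVWLGTFDTAEEAARAYDVAAREFRGPKAKTNF
>AP2_syn05 synthetic AP2-domain alignment member
SCYWGVRKRMGGKFAAEIRDPWKKTRVWLGTFDTAEEAARRYDVAAREFRGPKAKTNF
>AP2_syn06 synthetic AP2-domain alignment member
SGYGGTRKVPGGKFAAEIRDPWKKWRVWLGTFDTVEEAARAYDVAAEEFRGPKAKTNF
>AP2_syn07 synthetic AP2-domain alignment member
SGYGGVRKRPGGDFAAEIRDPWKKTRVWLGTFDTAEEAARFYDVAAREFRGGKAKTNF
>AP2_syn08 synthetic AP2-domain alignment member
SGYGGVRKRPGGKFAAEIRDPWKKREVPMHTFDTGEEAARAYDVAAREFRGPKAKTNF
>AP2_syn09 synthetic AP2-domain alignment member
SGYGGVRERPRGKFAAEIRDPWKKTRVWLGTFDTAELAARAYDVAAREFRGPKAKTNF
>AP2_syn10 synthetic AP2-domain alignment member
QGYGGVRKRPIWKFLAEIRDPWKKTPVWLGTFDTAEEAARAYDVAAHEFRGPKAWTNF
>AP2_syn11 synthetic AP2-domain alignment member
SGYGGVRKRPMGKFAAEIRDPWKKTRVWLGTFDTAEEAARAYDVAAREFRGPKAKTNF
>AP2_syn12 synthetic AP2-domain alignment member
SGYGGVRKRPGGVFAAEIRDPWKKTRVWLGTFDTACEAARAYDVAAREFRYPKAKTNF
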